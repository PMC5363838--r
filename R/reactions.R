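# Half-reactions, coupled metabolic reactions and conservation checks.

#' Define a half-reaction
#'
#' A stoichiometric map over compound ids; negative coefficients are
#' consumed, positive produced. Half-reactions are tagged catabolic (energy
#' generating) or anabolic (biomass forming).
#'
#' @param stoich Named numeric vector, `compound id -> coefficient`.
#' @param kind `"catabolic"` or `"anabolic"`.
#' @param compounds Compound registry (named list of [compound]); defaults
#'   to [default_compounds()].
#' @return Object of class `half_reaction`.
#' @export
half_reaction <- function(stoich, kind = c("catabolic", "anabolic"),
                          compounds = default_compounds()) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(stoich), !is.null(names(stoich)), all(nzchar(names(stoich))))
  unknown <- setdiff(names(stoich), names(compounds))
  if (length(unknown))
    stop("unknown compound id(s): ", paste(unknown, collapse = ", "))
  stoich <- stoich[stoich != 0]
  structure(list(stoich = stoich, kind = kind), class = "half_reaction")
}

#' @export
print.half_reaction <- function(x, ...) {
  cat(sprintf("<half_reaction:%s> %s\n", x$kind, format_stoich(x$stoich)))
  invisible(x)
}

format_stoich <- function(stoich) {
  lhs <- stoich[stoich < 0]; rhs <- stoich[stoich > 0]
  f <- function(s) paste(sprintf("%.4g %s", abs(unname(s)), names(s)), collapse = " + ")
  paste(f(lhs), "->", f(rhs))
}

# element + charge matrix (rows: C,H,O,N,S,charge) for a set of compound ids
conservation_matrix <- function(ids, compounds) {
  m <- vapply(ids, function(id) {
    cp <- compounds[[id]]
    c(cp$composition, charge = cp$charge)
  }, numeric(6))
  dim(m) <- c(6L, length(ids))
  dimnames(m) <- list(c("C", "H", "O", "N", "S", "charge"), ids)
  m
}

#' Check element and charge balance of a reaction
#'
#' @param reaction A [half_reaction], [metabolic_reaction], or a bare named
#'   stoichiometry vector.
#' @param compounds Compound registry.
#' @param tol Absolute tolerance on atom/charge counts (default 1e-9).
#' @return A data.frame of violations (`element`, `imbalance`); zero rows
#'   when the reaction balances.
#' @examples
#' r <- half_reaction(c(glucose = -1, O2 = -6, CO2 = 6, H2O = 6))
#' check_balance(r)   # empty: balanced combustion
#' @export
check_balance <- function(reaction, compounds = default_compounds(), tol = 1e-9) {
  stoich <- reaction_stoich(reaction)
  unknown <- setdiff(names(stoich), names(compounds))
  if (length(unknown))
    stop("unknown compound id(s): ", paste(unknown, collapse = ", "))
  M <- conservation_matrix(names(stoich), compounds)
  imbal <- drop(M %*% stoich)
  bad <- abs(imbal) > tol
  data.frame(element = names(imbal)[bad], imbalance = unname(imbal[bad]),
             stringsAsFactors = FALSE)
}

reaction_stoich <- function(reaction) {
  if (inherits(reaction, "half_reaction")) return(reaction$stoich)
  if (inherits(reaction, "metabolic_reaction")) return(reaction$net_stoich)
  if (is.numeric(reaction) && !is.null(names(reaction))) return(reaction[reaction != 0])
  stop("not a reaction object")
}

# Sum stoichiometry maps (named vectors), dropping zeros.
add_stoich <- function(...) {
  maps <- list(...)
  ids <- unique(unlist(lapply(maps, names)))
  out <- setNames(numeric(length(ids)), ids)
  for (m in maps) out[names(m)] <- out[names(m)] + m
  out[abs(out) > 1e-12]
}

#' Complete a reaction skeleton with balancing species
#'
#' Given fixed coefficients for the chemically interesting species, solves
#' for the coefficients of a set of balancing species (by default H2O, H+,
#' CO2 and NH4+) so that every element and the charge balance. Used to
#' write down half-reactions without hand-balancing water and protons.
#'
#' @param skeleton Named numeric vector of fixed coefficients.
#' @param balance_with Compound ids allowed to take any coefficient.
#' @param compounds Compound registry.
#' @return Balanced named stoichiometry vector.
#' @export
balance_skeleton <- function(skeleton,
                             balance_with = c("H2O", "H", "CO2", "NH4"),
                             compounds = default_compounds()) {
  balance_with <- setdiff(balance_with, names(skeleton))
  M_fix  <- conservation_matrix(names(skeleton), compounds)
  M_free <- conservation_matrix(balance_with, compounds)
  rhs <- -drop(M_fix %*% skeleton)
  # least-squares solve; must be an exact solution for a solvable skeleton
  x <- qr.solve(M_free, rhs, tol = 1e-12)
  full <- add_stoich(skeleton, setNames(x, balance_with))
  viol <- check_balance(full, compounds)
  if (nrow(viol))
    stop("skeleton cannot be balanced with {", paste(balance_with, collapse = ", "),
         "}: residual on ", paste(viol$element, collapse = ", "))
  full
}

#' Couple halves into a metabolic reaction (bookkeeping constructor)
#'
#' Low-level constructor combining an anabolic half (producing 1 C-mol
#' biomass) with `lambda_cat` times a catabolic half. Most users should call
#' [couple_halves()], which chooses `lambda_cat` from the energy balance.
#'
#' @param id Reaction label (the communal model uses letters a-v).
#' @param catabolic,anabolic [half_reaction]s; `anabolic` may be `NULL` for
#'   purely catabolic conversions (zero biomass yield).
#' @param lambda_cat Catabolic multiplier per C-mol biomass.
#' @param population Population bin label (`"A"`..`"F"`, or `"storage"`).
#' @param scenario `"sorted"`, `"unsorted"` or `"both"`.
#' @param compounds Compound registry.
#' @param biomass_id Compound id of biomass (or storage polymer) produced.
#' @param check If `TRUE` (default), an unbalanced net reaction is an
#'   error; loaders set `FALSE` to defer validation to a report.
#' @return Object of class `metabolic_reaction` with derived `net_stoich`
#'   and `yield_Y` (C-mol biomass per C-mol organic substrate consumed).
#' @export
metabolic_reaction <- function(id, catabolic, anabolic = NULL, lambda_cat = 1,
                               population = NA_character_,
                               scenario = c("both", "sorted", "unsorted"),
                               compounds = default_compounds(),
                               biomass_id = "biomass", check = TRUE) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(catabolic, "half_reaction"))
  if (!is.null(anabolic)) stopifnot(inherits(anabolic, "half_reaction"))
  net <- if (is.null(anabolic)) {
    lambda_cat <- 1
    catabolic$stoich
  } else {
    add_stoich(anabolic$stoich, lambda_cat * catabolic$stoich)
  }
  if (check) {
    viol <- check_balance(net, compounds)
    if (nrow(viol))
      stop("net reaction ", id, " unbalanced on ",
           paste(sprintf("%s (%.3g)", viol$element, viol$imbalance), collapse = ", "))
  }
  structure(
    list(id = id, catabolic = catabolic, anabolic = anabolic,
         lambda_cat = lambda_cat, net_stoich = net, population = population,
         scenario = scenario, yield_Y = reaction_yield(net, compounds, biomass_id)),
    class = "metabolic_reaction")
}

# C-mol biomass produced per C-mol organic substrate consumed in a net map.
reaction_yield <- function(net, compounds, biomass_id = "biomass") {
  x_ids <- names(net)[vapply(names(net), function(id)
    any(compounds[[id]]$roles %in% c("biomass", "storage")), logical(1))]
  xc <- sum(vapply(intersect(x_ids, biomass_id), function(id)
    max(net[id], 0) * compounds[[id]]$carbon_count, numeric(1)))
  organics <- setdiff(names(net)[net < 0 &
    vapply(names(net), function(id) compounds[[id]]$carbon_count > 0 &&
             id != "CO2", logical(1))], x_ids)
  sc <- sum(vapply(organics, function(id)
    -net[id] * compounds[[id]]$carbon_count, numeric(1)))
  if (sc <= 0) 0 else unname(xc / sc)
}

#' @export
print.metabolic_reaction <- function(x, ...) {
  cat(sprintf("<metabolic_reaction %s> bin %s, %s scenario\n  %s\n  lambda_cat = %.4g, Y = %.3f C-mol/C-mol\n",
              x$id, x$population, x$scenario, format_stoich(x$net_stoich),
              x$lambda_cat, x$yield_Y))
  invisible(x)
}
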