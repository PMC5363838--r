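# Fitting the communal metabolic model: non-negative reaction rates v >= 0
# minimizing || W (S v - observed) ||_2 + eps ||v||_2 over the reactions
# allowed in a scenario. This is the package's central model-fitting
# routine; it returns a classed object with the usual accessor methods.

#' Build the observed conversion vector for the study conditions
#'
#' Converts the medium to net conversion rates assuming the behaviour
#' reported for the assembled community: complete consumption of all
#' organic substrates and of nitrite and nitrate (denitrified to N2),
#' oxygen consumption equal to the pulsed supply, near-zero net turnover of
#' the cross-fed intermediates (formate, succinate, H2, sulfide, N2O) and a
#' small net export of elemental sulfur. Biomass is left unobserved (the
#' yield is a model output) unless `yield` is given.
#'
#' @param med A [medium].
#' @param o2_rate O2 consumption, mmol l^-1 day^-1; defaults to
#'   [oxygen_supply_rate()].
#' @param s0_export Net S0 export, mmol l^-1 day^-1 (default 30 uM * D).
#' @param yield Optional C-mol/C-mol community yield used to set an
#'   observed biomass production target.
#' @param compounds Compound registry.
#' @return A [conversion_vector].
#' @export
observed_conversions <- function(med = default_medium(),
                                 o2_rate = oxygen_supply_rate(),
                                 s0_export = 0.030 * med$dilution_rate,
                                 yield = NA_real_,
                                 compounds = default_compounds()) {
  sup <- supply_rates(med)$rates
  cc <- vapply(names(sup), function(id) compounds[[id]]$carbon_count, numeric(1))
  rates <- -sup[cc > 0]                                   # organics consumed
  n_to_n2 <- 0
  if ("NO2" %in% names(sup)) { rates["NO2"] <- -sup["NO2"]; n_to_n2 <- n_to_n2 + sup["NO2"] / 2 }
  if ("NO3" %in% names(sup)) { rates["NO3"] <- -sup["NO3"]; n_to_n2 <- n_to_n2 + sup["NO3"] / 2 }
  rates["N2"] <- n_to_n2
  rates["O2"] <- -o2_rate
  rates[c("formate", "succinate", "H2", "HS", "N2O", "SO4")] <- 0
  rates["S0"] <- s0_export
  biomass <- NA_real_
  if (!is.na(yield)) {
    total_c <- sum(sup[cc > 0] * cc[cc > 0])
    biomass <- yield * total_c
  }
  conversion_vector(rates, biomass_rate = biomass)
}

#' Fit reaction rates of a communal metabolic network
#'
#' Solves `min || W (S v - b) ||_2^2 + eps ||v||_2^2` subject to `v >= 0`
#' (Lawson-Hanson NNLS on the regularization-augmented system), where `S`
#' is the net stoichiometric matrix over the observed species, `b` the
#' observed net conversion rates and `W` diagonal weights. Species of the
#' network absent from `observed` (e.g. CO2, water, ammonium) are
#' unconstrained.
#'
#' @param network A [reaction_network].
#' @param observed A [conversion_vector] of net conversion rates
#'   (mmol l^-1 day^-1; negative = consumption).
#' @param scenario `"unsorted"`, `"sorted"` or `"all"`: which reactions are
#'   allowed (a reaction tagged `"both"` is allowed in either scenario).
#' @param weights Named vector of row weights, or `NULL` for the default
#'   relative weighting `1 / max(|observed|, floor)` with
#'   `floor = 0.01 * max |observed|`.
#' @param regularization Tikhonov parameter eps (default 1e-8) breaking
#'   ties in underdetermined networks toward the minimum-norm rate vector.
#' @param tie_basis Basis in which the tie-breaking norm is measured:
#'   `"cmol"` (default) rescales every reaction to one C-mol of organic
#'   substrate consumed (one 4-electron equivalent for carbon-free
#'   reactions) so that the selected member of the solution family does not
#'   depend on how reaction formula units happen to be written; `"unit"`
#'   uses the reactions as written.
#' @param fit_growth If `TRUE` and `observed$biomass_rate` is not `NA`, the
#'   biomass production rate is included as a fitting target; otherwise
#'   growth is a free model output.
#' @return Object of class `community_fit` with elements `rates`
#'   (mmol l^-1 day^-1 per reaction), `modeled` ([conversion_vector] over
#'   all network species), `residual_norm` (weighted L2), `population_growth`
#'   (C-mmol l^-1 day^-1 per bin), `abundances`, `community_yield`,
#'   `scenario`, and the inputs.
#' @examples
#' net <- default_network()
#' obs <- observed_conversions()
#' fit <- fit_community(net, obs, scenario = "unsorted")
#' fit$community_yield
#' @export
fit_community <- function(network, observed, scenario = c("unsorted", "sorted", "all"),
                          weights = NULL, regularization = 1e-8,
                          fit_growth = TRUE, tie_basis = c("cmol", "unit")) {
  scenario <- match.arg(scenario)
  tie_basis <- match.arg(tie_basis)
  stopifnot(inherits(network, "reaction_network"),
            inherits(observed, "conversion_vector"))
  allowed <- if (scenario == "all") network$reactions else
    Filter(function(r) r$scenario %in% c(scenario, "both"), network$reactions)
  if (!length(allowed)) stop("no reactions allowed in scenario '", scenario, "'")
  sub <- reaction_network(allowed, network$compounds)

  S_full <- stoich_matrix(sub)
  obs <- observed$rates
  target_biomass <- fit_growth && !is.na(observed$biomass_rate)
  species <- intersect(names(obs), rownames(S_full))
  if (!length(species)) stop("observed vector shares no species with the network")
  b <- obs[species]
  S <- S_full[species, , drop = FALSE]
  if (target_biomass) {
    S <- rbind(S, biomass_C = biomass_carbon_row(sub))
    b <- c(b, biomass_C = observed$biomass_rate)
  }

  if (all(b == 0)) {
    warning("all observed conversions are zero; returning zero rates")
    v <- setNames(numeric(ncol(S)), colnames(S))
  } else {
    scale <- if (tie_basis == "cmol") reaction_cmol_basis(sub) else
      setNames(rep(1, ncol(S)), colnames(S))
    w <- resolve_weights(weights, b)
    A <- rbind(sweep(S * w, 2, scale, "/"),
               sqrt(regularization) * diag(ncol(S)))
    rhs <- c(b * w, numeric(ncol(S)))
    sol <- pracma::lsqnonneg(A, rhs)
    v <- setNames(sol$x / scale, colnames(S))
  }

  modeled_full <- drop(stoich_matrix(sub) %*% v)
  w <- resolve_weights(weights, b)
  resid <- sqrt(sum((w * (drop(S %*% v) - b))^2))
  growth <- population_growth(sub, v)
  new_community_fit(v, modeled_full, resid, growth, scenario, sub, observed,
                    target_biomass)
}

# C-mol of organic substrate consumed per unit rate of each reaction (one
# 4-electron equivalent for carbon-free reactions): the common flux basis
# used for the tie-breaking norm.
reaction_cmol_basis <- function(network) {
  cps <- network$compounds
  vapply(network$reactions, function(r) {
    st <- r$net_stoich
    is_org <- vapply(names(st), function(id)
      cps[[id]]$carbon_count > 0 && id != "CO2", logical(1))
    org <- names(st)[st < 0 & is_org]
    c_cons <- if (length(org))
      sum(vapply(org, function(id) -st[[id]] * cps[[id]]$carbon_count, 0)) else 0
    if (c_cons > 1e-9) c_cons else {
      e <- sum(vapply(names(st), function(id)
        max(0, -st[[id]]) * abs(electrons_per_mol(cps[[id]])), 0))
      max(e / 4, 1e-6)
    }
  }, numeric(1))
}

# C-mol biomass produced per unit rate of each reaction
biomass_carbon_row <- function(network) {
  cc <- network$compounds[["biomass"]]$carbon_count
  vapply(network$reactions, function(r) {
    x <- r$net_stoich["biomass"]
    if (is.na(x)) 0 else unname(x) * cc
  }, numeric(1))
}

resolve_weights <- function(weights, b) {
  if (is.null(weights)) {
    floor_w <- 0.01 * max(abs(b), 1e-12)
    1 / pmax(abs(b), floor_w)
  } else {
    w <- rep(1, length(b)); names(w) <- names(b)
    hit <- intersect(names(weights), names(b))
    w[hit] <- weights[hit]
    w
  }
}

population_growth <- function(network, v) {
  cc <- network$compounds[["biomass"]]$carbon_count
  bins <- unique(vapply(network$reactions, `[[`, "", "population"))
  bins <- setdiff(bins, c(NA_character_, "storage"))
  out <- setNames(numeric(length(bins)), bins)
  for (r in network$reactions) {
    x <- r$net_stoich["biomass"]
    if (!is.na(x) && r$population %in% bins)
      out[r$population] <- out[r$population] + unname(x) * cc * v[r$id]
  }
  out
}

new_community_fit <- function(v, modeled, resid, growth, scenario, network,
                              observed, target_biomass) {
  cy <- tryCatch(yield_from_modeled(modeled, network$compounds),
                 error = function(e) NA_real_)
  ab <- if (any(growth > 0)) growth / sum(growth) else
    setNames(rep(NA_real_, length(growth)), names(growth))
  biomass_rate <- {
    x <- modeled["biomass"]
    if (is.na(x)) 0 else unname(x) * network$compounds[["biomass"]]$carbon_count
  }
  structure(list(rates = v, modeled = conversion_vector(modeled, biomass_rate),
                 residual_norm = resid, population_growth = growth,
                 abundances = ab, community_yield = cy, scenario = scenario,
                 network = network, observed = observed,
                 growth_targeted = target_biomass),
            class = "community_fit")
}

# community yield from a modeled conversion map: C-mol biomass produced per
# C-mol of net-consumed organic substrate (storage excluded from both).
yield_from_modeled <- function(modeled, compounds) {
  ids <- names(modeled)
  cc <- vapply(ids, function(id) compounds[[id]]$carbon_count, numeric(1))
  special <- vapply(ids, function(id)
    any(compounds[[id]]$roles %in% c("biomass", "storage")), logical(1))
  organic <- cc > 0 & !special & ids != "CO2"
  consumed <- sum(pmax(0, -modeled[organic]) * cc[organic])
  if (consumed <= 1e-12) stop("no net organic carbon consumption in the model")
  produced <- if ("biomass" %in% ids) max(0, modeled[["biomass"]]) *
    compounds[["biomass"]]$carbon_count else 0
  produced / consumed
}

#' Community biomass yield of a fit
#'
#' Total C-mol biomass produced per C-mol of net organic substrate
#' consumed (storage-polymer carbon counts in neither numerator nor
#' denominator).
#'
#' @param fit A [community_fit()][fit_community] object.
#' @return C-mol/C-mol yield.
#' @export
community_yield <- function(fit) {
  stopifnot(inherits(fit, "community_fit"))
  if (is.na(fit$community_yield))
    stop("no net organic carbon consumption in the fitted model")
  fit$community_yield
}

#' Relative population abundances of a fit
#'
#' Growth share of each population bin: `growth_b / sum(growth)`, with the
#' storage flux excluded (storage is not assigned to any population).
#'
#' @param fit A `community_fit`.
#' @return Named vector of fractions summing to 1.
#' @export
population_abundances <- function(fit) {
  stopifnot(inherits(fit, "community_fit"))
  g <- fit$population_growth
  if (all(g <= 0)) stop("no population grows in the fitted model")
  g / sum(g)
}

#' Compare the sorted and unsorted scenarios on the same observations
#'
#' Fits both scenarios and reports yields, abundances and residual norms
#' side by side, flagging the scenario that better matches the
#' observations (lower weighted residual).
#'
#' @param network A [reaction_network].
#' @param observed A [conversion_vector].
#' @param ... Passed to [fit_community()].
#' @return Object of class `scenario_comparison`: list with both fits and a
#'   summary data.frame.
#' @export
scenario_compare <- function(network, observed, ...) {
  fits <- list(sorted = fit_community(network, observed, "sorted", ...),
               unsorted = fit_community(network, observed, "unsorted", ...))
  tab <- data.frame(
    scenario = names(fits),
    residual_norm = vapply(fits, `[[`, 0, "residual_norm"),
    community_yield = vapply(fits, `[[`, 0, "community_yield"),
    row.names = NULL)
  structure(list(fits = fits, summary = tab,
                 best = tab$scenario[which.min(tab$residual_norm)]),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("<scenario_comparison>\n")
  print(x$summary, row.names = FALSE)
  cat("better match (lower residual):", x$best, "\n")
  invisible(x)
}

# ---- methods ----------------------------------------------------------------

#' @export
print.community_fit <- function(x, ...) {
  cat(sprintf("<community_fit> scenario '%s', %d reactions\n", x$scenario,
              length(x$rates)))
  cat(sprintf("  residual norm (weighted): %.4g\n", x$residual_norm))
  cat(sprintf("  community yield: %.3f C-mol/C-mol\n", x$community_yield))
  cat("  abundances:",
      paste(sprintf("%s=%.2f", names(x$abundances), x$abundances), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
summary.community_fit <- function(object, ...) {
  en <- yield_report(object$network$reactions)
  en$rate <- object$rates[en$id]
  structure(list(fit = object, reactions = en), class = "summary.community_fit")
}

#' @export
print.summary.community_fit <- function(x, ...) {
  print(x$fit)
  cat("\nReaction rates (mmol/l/day) and energetics:\n")
  tab <- x$reactions[, c("id", "population", "yield_Y", "rate")]
  print(tab[order(-tab$rate), ], row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.community_fit <- function(object, ...) object$rates

#' @export
fitted.community_fit <- function(object, ...) object$modeled

#' @export
residuals.community_fit <- function(object, ...) {
  obs <- object$observed$rates
  mod <- object$modeled$rates
  species <- intersect(names(obs), names(mod))
  obs[species] - mod[species]
}

#' Predict net conversions for a rate vector
#'
#' @param object A `community_fit`.
#' @param rates Optional named rate vector; defaults to the fitted rates.
#' @param ... Unused.
#' @return A [conversion_vector] of modeled net conversions.
#' @export
predict.community_fit <- function(object, rates = NULL, ...) {
  v <- if (is.null(rates)) object$rates else {
    stopifnot(!is.null(names(rates)))
    out <- setNames(numeric(length(object$rates)), names(object$rates))
    out[intersect(names(rates), names(out))] <- rates[intersect(names(rates), names(out))]
    out
  }
  modeled <- drop(stoich_matrix(object$network) %*% v)
  cc <- object$network$compounds[["biomass"]]$carbon_count
  b <- if ("biomass" %in% names(modeled)) unname(modeled["biomass"]) * cc else 0
  conversion_vector(modeled, b)
}

#' Plot a community fit
#'
#' Two base-graphics panels: modeled vs observed net conversions, and
#' relative population abundances.
#'
#' @param x A `community_fit`.
#' @param ... Unused.
#' @export
plot.community_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  obs <- x$observed$rates
  mod <- x$modeled$rates
  species <- intersect(names(obs), names(mod))
  m <- rbind(observed = obs[species], modeled = mod[species])
  graphics::barplot(m, beside = TRUE, las = 2, col = c("grey30", "steelblue"),
                    ylab = "net conversion (mmol/l/day)",
                    main = paste0("scenario: ", x$scenario))
  graphics::legend("bottomright", legend = rownames(m), bty = "n",
                   fill = c("grey30", "steelblue"))
  graphics::barplot(x$abundances, ylab = "relative abundance", las = 1,
                    col = "tan", main = "population bins")
  invisible(x)
}
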