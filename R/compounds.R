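# Compounds: elemental composition, charge, standard Gibbs energy of
# formation at pH 7 (kJ/mol), and the degree-of-reduction bookkeeping.

#' Parse a molecular formula string
#'
#' Turns a Hill-style formula such as `"C6H12O6"` into a named vector of
#' element counts. Only C, H, O, N and S are tracked; fractional counts
#' (e.g. the C-mol biomass formula `"CH1.8O0.5N0.2"`) are allowed.
#'
#' @param formula Character scalar, e.g. `"C6H12O6"`.
#' @return Named numeric vector over elements `c("C","H","O","N","S")`.
#' @examples
#' parse_formula("CH1.8O0.5N0.2")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  out <- c(C = 0, H = 0, O = 0, N = 0, S = 0)
  if (formula == "e") return(out)  # massless placeholder
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  for (p in parts) {
    el <- sub("^([A-Z][a-z]?).*$", "\\1", p)
    n  <- sub("^[A-Z][a-z]?", "", p)
    if (!el %in% names(out))
      stop("unsupported element '", el, "' in formula ", formula)
    out[el] <- out[el] + if (nzchar(n)) as.numeric(n) else 1
  }
  out
}

#' Define a chemical compound
#'
#' @param id Short name used in reactions and tables (e.g. `"glucose"`).
#' @param formula Formula string over C/H/O/N/S, e.g. `"C2H3O2"` for the
#'   acetate ion (the charge is given separately).
#' @param charge Net charge of the species.
#' @param dGf0 Standard Gibbs energy of formation at pH 7 and 25 degC,
#'   kJ/mol (kJ/C-mol for biomass-type compounds defined per carbon).
#'   `NA` is allowed for species never used in an energy calculation.
#' @param roles Character vector of role tags (`"substrate"`, `"product"`,
#'   `"electron-acceptor"`, `"biomass"`, `"storage"`).
#' @return An object of class `compound`.
#' @export
compound <- function(id, formula, charge = 0, dGf0 = NA_real_, roles = character()) {
  stopifnot(is.character(id), length(id) == 1L)
  comp <- parse_formula(formula)
  structure(
    list(id = id, formula = formula, composition = comp, charge = charge,
         dGf0_prime = dGf0, carbon_count = unname(comp["C"]), roles = roles),
    class = "compound")
}

#' @export
print.compound <- function(x, ...) {
  cat(sprintf("<compound> %s (%s%s), dGf0' = %s kJ/mol\n", x$id, x$formula,
              if (x$charge != 0) sprintf(", charge %+d", x$charge) else "",
              ifelse(is.na(x$dGf0_prime), "NA", format(x$dGf0_prime))))
  invisible(x)
}

# Conventional valences for degree-of-reduction bookkeeping, referenced to
# CO2 / H2O / NH4+ / H2S: C +4, H +1, O -2, N -3, S -2. The ionic charge is
# subtracted (an electron kept by the ion is an available electron).
.gamma_valence <- c(C = 4, H = 1, O = -2, N = -3, S = -2)

#' Degree of reduction of a compound
#'
#' Available electrons per C-mol, gamma = (4C + H - 2O - 3N - 2S - charge)/C,
#' with nitrogen referenced to ammonium and organic sulfur (as in methionine)
#' at the sulfide level. Glucose and acetate give 4; the standard biomass
#' formula CH1.8O0.5N0.2 gives 4.2.
#'
#' @param x A [compound].
#' @return Dimensionless electrons per C-mol.
#' @export
degree_of_reduction <- function(x) {
  stopifnot(inherits(x, "compound"))
  if (x$carbon_count < 1)
    stop("gamma undefined for C0 compounds: ", x$id)
  e <- sum(.gamma_valence * x$composition) - x$charge
  e / x$carbon_count
}

#' Electrons per formula unit (gamma times carbon count)
#'
#' Like [degree_of_reduction()] but per mole of compound and defined for
#' carbon-free species as well (e.g. H2 gives 2, O2 gives -4).
#' @param x A [compound].
#' @return Available electrons per mole.
#' @export
electrons_per_mol <- function(x) {
  stopifnot(inherits(x, "compound"))
  sum(.gamma_valence * x$composition) - x$charge
}

#' Built-in compound table
#'
#' The compounds of the tidal-chemostat medium and of the default communal
#' metabolic network, with standard Gibbs energies of formation at pH 7 and
#' 25 degC (kJ/mol) from standard biochemical compilations. Amino-acid
#' values are approximate compilation values; biomass is the conventional
#' CH1.8O0.5N0.2 at -67 kJ/C-mol; `storage` is a glycogen-like glucan
#' written per C-mol.
#'
#' @return Named list of [compound] objects.
#' @export
default_compounds <- function() {
  defs <- list(
    #          id            formula          charge  dGf0'    roles
    list("glucose",    "C6H12O6",       0, -917.22, c("substrate")),
    list("acetate",    "C2H3O2",       -1, -369.41, c("substrate", "product")),
    list("glutamate",  "C5H8NO4",      -1, -699.60, c("substrate")),
    list("aspartate",  "C4H6NO4",      -1, -700.40, c("substrate")),
    list("alanine",    "C3H7NO2",       0, -371.50, c("substrate")),
    list("serine",     "C3H7NO3",       0, -510.90, c("substrate")),
    list("tyrosine",   "C9H11NO3",      0, -387.10, c("substrate")),
    list("histidine",  "C6H9N3O2",      0, -226.20, c("substrate")),
    list("methionine", "C5H11NO2S",     0, -502.90, c("substrate")),
    list("formate",    "CHO2",         -1, -351.04, c("product", "substrate")),
    list("succinate",  "C4H4O4",       -2, -690.23, c("product", "substrate")),
    list("H2",         "H2",            0,    0.00, c("product", "substrate")),
    list("O2",         "O2",            0,    0.00, c("electron-acceptor")),
    list("NO3",        "NO3",          -1, -111.34, c("electron-acceptor")),
    list("NO2",        "NO2",          -1,  -32.22, c("electron-acceptor")),
    list("N2",         "N2",            0,    0.00, c("product")),
    list("N2O",        "N2O",           0,  104.18, c("product")),
    list("NH4",        "NH4",           1,  -79.37, c("product", "substrate")),
    list("SO4",        "SO4",          -2, -744.63, c("electron-acceptor")),
    list("HS",         "HS",           -1,   12.05, c("product", "substrate")),
    list("S0",         "S",             0,    0.00, c("product")),
    list("CO2",        "CO2",           0, -394.36, c("product")),
    list("H2O",        "H2O",           0, -237.18, character()),
    list("H",          "H",             1,  -39.87, character()),
    list("biomass",    "CH1.8O0.5N0.2", 0,  -67.00, c("biomass")),
    # glycogen-like glucan written per anhydroglucose unit (glucose - H2O)
    list("storage",    "C6H10O5",       0, -680.04, c("storage"))
  )
  out <- lapply(defs, function(d) compound(d[[1]], d[[2]], d[[3]], d[[4]], d[[5]]))
  names(out) <- vapply(out, `[[`, "", "id")
  out
}
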