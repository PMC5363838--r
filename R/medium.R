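# Medium composition, supply fluxes and chemostat arithmetic.

#' Define a chemostat medium
#'
#' @param concentrations Named numeric vector, compound id -> mM.
#' @param dilution_rate Dilution rate, per day.
#' @return Object of class `medium`.
#' @export
medium <- function(concentrations, dilution_rate) {
  stopifnot(is.numeric(concentrations), !is.null(names(concentrations)),
            all(concentrations >= 0), length(dilution_rate) == 1L,
            dilution_rate > 0)
  structure(list(concentrations = concentrations, dilution_rate = dilution_rate),
            class = "medium")
}

#' The tidal-chemostat medium
#'
#' The printed medium of the study system: 20.0 mM nitrite, 1.0 mM nitrate,
#' 6.0 mM glucose, 3.1 mM acetate and seven amino acids (glutamate 1.1,
#' aspartate 1.5, alanine 1.5, serine 0.80, tyrosine 0.51, histidine 0.12,
#' methionine 0.25 mM), supplied at a dilution rate of 0.26 per day.
#' Inorganic salts that do not enter the carbon/nitrogen bookkeeping
#' (phosphate, trace metals, sea salts) are omitted; seawater sulfate is
#' carried at 28 mM as the sulfate-reduction acceptor.
#'
#' @return A [medium].
#' @export
default_medium <- function() {
  medium(c(NO2 = 20.0, NO3 = 1.0, glucose = 6.0, acetate = 3.1,
           glutamate = 1.1, aspartate = 1.5, alanine = 1.5, serine = 0.80,
           tyrosine = 0.51, histidine = 0.12, methionine = 0.25, SO4 = 28),
         dilution_rate = 0.26)
}

#' Carbon fractions of the supplied medium
#'
#' Fraction of supplied carbon (C-mol basis) contributed by each compound
#' group. For the default medium glucose carries ~54% and acetate ~9% of
#' the supplied carbon, matching the printed ~50%/~10% description.
#'
#' @param med A [medium].
#' @param grouping Optional named character vector mapping compound ids to
#'   group labels; ungrouped carbon compounds form their own group.
#' @param compounds Compound registry.
#' @return Named numeric vector of fractions summing to 1.
#' @export
carbon_fractions <- function(med, grouping = NULL, compounds = default_compounds()) {
  stopifnot(inherits(med, "medium"))
  conc <- med$concentrations
  cc <- vapply(names(conc), function(id) {
    if (!id %in% names(compounds)) stop("unknown compound id: ", id)
    compounds[[id]]$carbon_count
  }, numeric(1))
  cmol <- conc * cc
  cmol <- cmol[cmol > 0]
  if (!length(cmol)) stop("medium contains no carbon")
  grp <- names(cmol)
  if (!is.null(grouping)) {
    hit <- names(cmol) %in% names(grouping)
    grp[hit] <- grouping[names(cmol)[hit]]
  }
  fr <- tapply(cmol, grp, sum) / sum(cmol)
  out <- as.numeric(fr); names(out) <- names(fr)
  out
}

#' Supply fluxes of a medium
#'
#' Converts medium concentrations to supply rates: concentration (mM) times
#' dilution rate (per day) gives mmol l^-1 day^-1.
#'
#' @param med A [medium].
#' @return A [conversion_vector] of (positive) supply rates.
#' @export
supply_rates <- function(med) {
  stopifnot(inherits(med, "medium"))
  conversion_vector(med$concentrations * med$dilution_rate)
}

#' Number of microbial generations in a chemostat run
#'
#' At steady state the specific growth rate equals the dilution rate, so
#' the number of doublings is `duration * D / ln 2`. 100 days at 0.26 per
#' day gives ~37.5 generations.
#'
#' @param duration_days Run length, days.
#' @param dilution_rate Dilution rate, per day.
#' @return Generation (doubling) count.
#' @export
generations <- function(duration_days, dilution_rate) {
  if (!is.numeric(duration_days) || duration_days <= 0 ||
      !is.numeric(dilution_rate) || dilution_rate <= 0)
    stop("duration and dilution rate must be positive")
  duration_days * dilution_rate / log(2)
}

#' Conversion-rate vector
#'
#' Net conversion rates per compound, mmol l^-1 day^-1 (negative = net
#' consumption), optionally with a biomass production rate in
#' C-mmol l^-1 day^-1.
#'
#' @param rates Named numeric vector.
#' @param biomass_rate Biomass production, C-mmol l^-1 day^-1, or `NA`.
#' @return Object of class `conversion_vector`.
#' @export
conversion_vector <- function(rates, biomass_rate = NA_real_) {
  stopifnot(is.numeric(rates), !is.null(names(rates)) || length(rates) == 0,
            all(is.finite(rates)))
  structure(list(rates = rates, biomass_rate = biomass_rate),
            class = "conversion_vector")
}

#' @export
print.conversion_vector <- function(x, ...) {
  cat("<conversion_vector> mmol/l/day\n")
  if (length(x$rates)) print(round(x$rates, 4))
  if (!is.na(x$biomass_rate))
    cat(sprintf("biomass: %.4g C-mmol/l/day\n", x$biomass_rate))
  invisible(x)
}

#' Oxygen supply rate of the pulsed-gas regime
#'
#' Pure oxygen supplied at a given gas flow for a fixed duration once per
#' cycle, converted to a culture-volume specific molar rate assuming ideal
#' gas at the culture temperature and complete utilisation. Defaults are
#' the tidal regime: 20 ml/min for 5 min every 12 h into 2.8 l at 25 degC,
#' i.e. ~2.9 mmol O2 l^-1 day^-1.
#'
#' @param flow_ml_min Gas flow, ml/min.
#' @param pulse_min Pulse duration, minutes.
#' @param period_h Cycle period, hours.
#' @param volume_l Culture volume, litres.
#' @param temperature_K Gas temperature.
#' @return mmol O2 per litre per day.
#' @export
oxygen_supply_rate <- function(flow_ml_min = 20, pulse_min = 5, period_h = 12,
                               volume_l = 2.8, temperature_K = 298.15) {
  ml_per_day <- flow_ml_min * pulse_min * (24 / period_h)
  mol <- 101325 * (ml_per_day * 1e-6) / (8.314462 * temperature_K)  # ideal gas
  1000 * mol / volume_l
}
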