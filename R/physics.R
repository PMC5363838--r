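# Diffusion-limited oxygen supply to suspended cells and microaggregates.
# Quasi-steady spherical diffusion through a finite static boundary layer:
#   J = 4 pi D * (r R / (R - r)) * ([O2]_bulk - [O2]_surface)
# For R -> Inf this reduces to the classic 4 pi D r dC single-cell limit.

#' Unit constants for oxygen calculations
#'
#' `uM_to_mol_m3` (1 uM = 1e-3 mol/m^3) and `air_saturation_uM` (~20 uM
#' dissolved O2 at ~10% air saturation, the regime of interest).
#' @export
oxygen_units <- c(uM_to_mol_m3 = 1e-3, air_saturation_10pct_uM = 20)

#' Diffusive flux of oxygen toward a cell or aggregate
#'
#' @param r_obj Radius of the cell or aggregate, m (must be < `R_bl`).
#' @param C_bulk Bulk concentration, mol/m^3.
#' @param C_surf Concentration at the object surface, mol/m^3 (0 when
#'   uptake is diffusion limited).
#' @param D_diff Diffusion coefficient, m^2/s (default 1e-9).
#' @param R_bl Static boundary-layer radius, m (default 1e-5, the
#'   Kolmogorov scale in turbulent systems); `Inf` gives the unbounded
#'   single-sphere limit `4 pi D r dC`.
#' @return Flux toward the object, mol/s.
#' @examples
#' diffusive_flux(0.5e-6, C_bulk = 0.02)  # 1 um cell, 20 uM O2
#' @export
diffusive_flux <- function(r_obj, C_bulk, C_surf = 0, D_diff = 1e-9, R_bl = 1e-5) {
  stopifnot(r_obj > 0, C_bulk >= 0, C_surf >= 0, D_diff > 0)
  if (is.finite(R_bl) && r_obj >= R_bl)
    stop("object radius must be smaller than the boundary-layer radius")
  geom <- if (is.finite(R_bl)) r_obj * R_bl / (R_bl - r_obj) else r_obj
  4 * pi * D_diff * geom * (C_bulk - C_surf)
}

#' Bulk concentration at which diffusive supply equals demand
#'
#' The depletion threshold: with zero surface concentration, the bulk
#' concentration at which the diffusive flux just matches the uptake rate,
#' `C* = uptake / (4 pi D r R / (R - r))`. A 1-um cell respiring 25
#' fmol/day depletes its surroundings only below ~44 nM bulk O2; an
#' aggregate of N such cells needs roughly N times more.
#'
#' @param uptake Uptake rate of the cell or aggregate, mol/s.
#' @param r_obj,D_diff,R_bl As in [diffusive_flux()].
#' @return Bulk concentration threshold, mol/m^3.
#' @export
depletion_threshold <- function(uptake, r_obj, D_diff = 1e-9, R_bl = 1e-5) {
  if (uptake <= 0) stop("uptake must be positive")
  stopifnot(r_obj > 0, D_diff > 0)
  if (is.finite(R_bl) && r_obj >= R_bl)
    stop("object radius must be smaller than the boundary-layer radius")
  geom <- if (is.finite(R_bl)) r_obj * R_bl / (R_bl - r_obj) else r_obj
  uptake / (4 * pi * D_diff * geom)
}

#' Convert a protein-specific uptake rate to fmol per cell per day
#'
#' `specific_rate` (mmol O2 per g protein per hour) times the protein
#' content per cell times 24 h. The default protein content (5.2e-14 g) is
#' back-calculated so that the community's maximal measured 20 mmol g^-1
#' protein h^-1 corresponds to ~25 fmol per day for a 1-um spherical cell;
#' it is a documented convention, not a measurement.
#'
#' @param specific_rate mmol O2 / g protein / h.
#' @param protein_per_cell g protein per cell.
#' @param cells Number of cells (for an aggregate total).
#' @return fmol O2 per day (per cell when `cells = 1`).
#' @export
uptake_per_cell <- function(specific_rate, protein_per_cell = 5.2e-14, cells = 1) {
  stopifnot(specific_rate >= 0, protein_per_cell > 0, cells >= 1)
  # mmol/g/h * g * 24 h = mmol/day -> 1e12 fmol/mmol
  specific_rate * protein_per_cell * 24 * 1e12 * cells
}

#' fmol per day to mol per second
#'
#' Convenience converter for feeding [uptake_per_cell()] output into
#' [depletion_threshold()].
#' @param fmol_per_day Rate in fmol/day.
#' @return mol/s.
#' @export
fmol_day_to_mol_s <- function(fmol_per_day) fmol_per_day * 1e-15 / 86400
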