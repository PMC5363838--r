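# Synthetic-data generators: a tidal-cycle chemostat ODE simulator, noisy
# conversion vectors from a known true rate vector, and multinomial
# read-count tables from known per-ORF activities. All generators are pure
# functions of (parameters, seed).

#' Parameters of the tidal-cycle chemostat simulator
#'
#' Mass-balance ODE model of the oxygen-pulsed chemostat: continuous medium
#' supply and washout at the dilution rate, a square oxygen pulse once per
#' cycle, first-order gas stripping, and Monod-type community kinetics for
#' fermentation, aerobic respiration, two-step denitrification
#' (nitrite -> N2O -> N2) and a sulfur mini-cycle. Kinetic constants are
#' not measured quantities of the study system; the defaults are chosen so
#' that the oxygen window lasts about 2 h and nitrite, formate and S0 move
#' on the scales reported for the system.
#'
#' @param med A [medium] (nitrite/nitrate/carbon concentrations, dilution).
#' @param o2_pulse_mM O2 added per pulse, mM dissolved-equivalent
#'   (default 0.030 = 30 uM).
#' @param o2_pulse_min Pulse duration, minutes (default 5).
#' @param period_h Cycle period, hours (default 12).
#' @param vmax Named vector of maximal volumetric rates (mM/h): `o2`
#'   (aerobic respiration), `no3` (nitrate -> nitrite), `no2` (nitrite ->
#'   N2O), `n2o` (N2O -> N2), `ferm` (fermentation, C basis), `cons`
#'   (half-saturation scale of respiratory product consumption), `s0`
#'   (sulfide -> S0), `s0red` (S0 re-reduction).
#' @param km Named vector of half-saturation constants (mM) for the same
#'   processes plus `o2_inhib` (O2 inhibition of N2O reduction and of
#'   formate consumption in redox-tower mode).
#' @param strip Gas stripping rate constants per hour for O2, N2, N2O.
#' @param redox_tower If `TRUE`, anaerobic processes (denitrification,
#'   S0 reduction) are suppressed above the O2 inhibition constant -- the
#'   thermodynamically sorted null model. Default `FALSE` (braided mode:
#'   all processes run whenever their substrates are present).
#' @return Object of class `chemostat_params`.
#' @export
chemostat_params <- function(med = default_medium(),
                             o2_pulse_mM = 0.030, o2_pulse_min = 5,
                             period_h = 12,
                             vmax = c(o2 = 0.022, no3 = 0.05, no2 = 0.5,
                                      n2o = 0.12, ferm = 0.30, cons = 0.35,
                                      s0 = 0.004, s0red = 0.002),
                             km = c(o2 = 0.001, no2 = 0.005, n2o = 0.002,
                                    ferm = 0.5, cons = 0.3, s0 = 0.01,
                                    o2_inhib = 0.002),
                             strip = c(O2 = 0.05, N2 = 0.4, N2O = 0.3),
                             redox_tower = FALSE) {
  stopifnot(inherits(med, "medium"), all(vmax >= 0), all(km > 0),
            all(strip >= 0), o2_pulse_mM >= 0, o2_pulse_min > 0, period_h > 0)
  structure(list(med = med, o2_pulse_mM = o2_pulse_mM,
                 o2_pulse_min = o2_pulse_min, period_h = period_h,
                 vmax = vmax, km = km, strip = strip,
                 redox_tower = redox_tower),
            class = "chemostat_params")
}

#' Simulate tidal cycles of the chemostat
#'
#' Integrates the mass balances over `n_cycles` oxygen pulses with a
#' stiff-capable solver (lsoda, rtol 1e-8) and returns the concentration
#' trajectories together with the cumulative electron balance
#' `delta_e = electrons donated - electrons accepted` (the braided system
#' runs a standing electron imbalance within each cycle, closed by storage).
#'
#' @param params A [chemostat_params].
#' @param n_cycles Number of 12-h cycles to integrate (default 2).
#' @param dt Output time step, hours.
#' @param noise_sd Relative s.d. of optional multiplicative observation
#'   noise (0 = none).
#' @param seed Integer seed for the observation noise.
#' @return data.frame: `time_h`, concentration columns (mM: O2, NO2, NO3,
#'   N2, N2O, formate, acetate, succinate, S0, biomass), `e_donated`,
#'   `e_accepted`, `delta_e` (mmol electrons per litre).
#' @export
simulate_cycle <- function(params = chemostat_params(), n_cycles = 2,
                           dt = 0.02, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(params, "chemostat_params"), n_cycles >= 1)
  p <- params
  D <- p$med$dilution_rate / 24          # per hour
  conc <- p$med$concentrations
  feed <- function(id) if (id %in% names(conc)) conc[[id]] else 0
  # carbon feed (mM C/h) fuelling fermentation
  cps <- default_compounds()
  cmol <- vapply(names(conc), function(id)
    conc[[id]] * cps[[id]]$carbon_count, numeric(1))
  cfeed <- sum(cmol) * D
  # supply-weighted mean degree of reduction of the fed carbon
  gammas <- vapply(names(conc)[cmol > 0], function(id)
    degree_of_reduction(cps[[id]]), numeric(1))
  gamma_feed <- sum(gammas * cmol[cmol > 0]) / sum(cmol)
  pulse_h <- p$o2_pulse_min / 60
  pulse_rate <- p$o2_pulse_mM / pulse_h   # mM/h during the pulse

  state <- c(O2 = 0, NO2 = 0.005, NO3 = 0.002, N2 = 0, N2O = 0,
             formate = 0.3, acetate = 0.2, succinate = 0.05, S0 = 0.01,
             biomass = 20, Cpool = 1, e_donated = 0, e_accepted = 0)

  monod <- function(s, k) s / (k + s)
  deriv <- function(t, y, parms) {
    y <- pmax(y, 0)
    tc <- t %% p$period_h
    o2_in <- if (tc < pulse_h) pulse_rate else 0
    anox <- if (p$redox_tower) p$km[["o2_inhib"]] / (p$km[["o2_inhib"]] + y[["O2"]]) else 1
    nos_ok <- p$km[["o2_inhib"]] / (p$km[["o2_inhib"]] + y[["O2"]])  # N2O reductase is O2 sensitive

    r_ferm <- p$vmax[["ferm"]] * monod(y[["Cpool"]], p$km[["ferm"]])      # mM C/h
    r_o2   <- p$vmax[["o2"]]   * monod(y[["O2"]], p$km[["o2"]]) *
              monod(y[["formate"]] + y[["acetate"]] + y[["succinate"]], p$km[["cons"]])
    r_no3  <- p$vmax[["no3"]]  * monod(y[["NO3"]], p$km[["no2"]]) * anox  # NO3- -> NO2-, mM N/h
    r_no2  <- p$vmax[["no2"]]  * monod(y[["NO2"]], p$km[["no2"]]) * anox  # NO2- -> 1/2 N2O, mM N/h
    r_n2o  <- p$vmax[["n2o"]]  * monod(y[["N2O"]], p$km[["n2o"]]) * nos_ok * anox  # mM N2O/h
    r_s0   <- p$vmax[["s0"]]   * monod(y[["O2"]], p$km[["o2"]])           # sulfide -> S0
    r_s0r  <- p$vmax[["s0red"]] * monod(y[["S0"]], p$km[["s0"]]) * anox

    # respiratory carbon consumption (mM C/h): electron flow / 4 e- per C,
    # split over the fermentation-product pools in proportion to pool size
    tot <- y[["formate"]] + y[["acetate"]] + y[["succinate"]] + 1e-12
    c_resp <- (4 * r_o2 + 2 * r_no3 + 3 * r_no2 + 2 * r_n2o) / 4
    f_share <- y[["formate"]] / tot; a_share <- y[["acetate"]] / tot
    s_share <- y[["succinate"]] / tot

    yield_ferm <- 0.14; yield_resp <- 0.33
    growth <- yield_ferm * r_ferm + yield_resp * c_resp

    d <- numeric(length(y)); names(d) <- names(y)
    d[["Cpool"]]   <- cfeed - r_ferm - D * y[["Cpool"]]
    d[["O2"]]      <- o2_in - r_o2 - (p$strip[["O2"]] + D) * y[["O2"]]
    d[["NO2"]]     <- feed("NO2") * D + r_no3 - r_no2 - D * y[["NO2"]]
    d[["NO3"]]     <- feed("NO3") * D - r_no3 - D * y[["NO3"]]
    d[["N2O"]]     <- r_no2 / 2 - r_n2o - p$strip[["N2O"]] * y[["N2O"]]
    d[["N2"]]      <- r_n2o - p$strip[["N2"]] * y[["N2"]]
    prod_c <- r_ferm * (1 - yield_ferm)
    d[["formate"]]   <- 0.35 * prod_c / 1 - c_resp * f_share - D * y[["formate"]]
    d[["acetate"]]   <- 0.45 * prod_c / 2 - c_resp * a_share / 2 - D * y[["acetate"]]
    d[["succinate"]] <- 0.20 * prod_c / 4 - c_resp * s_share / 4 - D * y[["succinate"]]
    d[["S0"]]      <- r_s0 - r_s0r - D * y[["S0"]]
    d[["biomass"]] <- growth - D * y[["biomass"]]
    # cumulative electron audit over the C/O2/N system (the sulfur tracer
    # mini-cycle is excluded): donors are the fed carbon substrates at the
    # supply mean degree of reduction; acceptors O2, NO3-, NO2-, N2O
    d[["e_donated"]]  <- gamma_feed * cfeed
    d[["e_accepted"]] <- 4 * r_o2 + 2 * r_no3 + 3 * r_no2 + 2 * r_n2o
    list(d)
  }

  times <- seq(0, n_cycles * p$period_h, by = dt)
  sol <- deSolve::ode(y = state, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop("integrator failure; final state: ",
         paste(sprintf("%s=%.3g", colnames(sol)[-1], sol[nrow(sol), -1]),
               collapse = ", "))
  out <- as.data.frame(sol)
  names(out)[1] <- "time_h"
  out$delta_e <- out$e_donated - out$e_accepted
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    traj <- setdiff(names(out), c("time_h", "e_donated", "e_accepted", "delta_e"))
    for (cn in traj)
      out[[cn]] <- out[[cn]] * (1 + stats::rnorm(nrow(out), 0, noise_sd))
  }
  out
}

#' Generate an observed conversion vector from known true rates
#'
#' Computes the noise-free net conversions `S v*` of a network for a known
#' rate vector and adds seeded Gaussian noise of relative standard
#' deviation `noise_sd`, giving ground-truth test inputs for
#' [fit_community()].
#'
#' @param network A [reaction_network].
#' @param true_rates Named non-negative rate vector over (a subset of) the
#'   network's reactions, mmol l^-1 day^-1.
#' @param noise_sd Relative noise s.d. (0 = exact).
#' @param seed Integer seed.
#' @return A [conversion_vector] over the network's species (water and
#'   protons excluded), with the implied biomass rate.
#' @export
generate_observations <- function(network, true_rates, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(network, "reaction_network"), all(true_rates >= 0),
            !is.null(names(true_rates)))
  unknown <- setdiff(names(true_rates), names(network$reactions))
  if (length(unknown)) stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  v <- setNames(numeric(length(network$reactions)), names(network$reactions))
  v[names(true_rates)] <- true_rates
  modeled <- drop(stoich_matrix(network) %*% v)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    modeled <- modeled * (1 + stats::rnorm(length(modeled), 0, noise_sd))
  }
  cc <- network$compounds[["biomass"]]$carbon_count
  b <- if ("biomass" %in% names(modeled)) unname(modeled["biomass"]) * cc else NA_real_
  conversion_vector(modeled, b)
}

#' Generate a read-count table from known per-ORF activities
#'
#' Draws `depth` reads from a multinomial with per-ORF probability
#' proportional to activity x length. Within each bin the true activities
#' are first renormalized so that their ORF-length-weighted mean is 1 (the
#' scale [transcriptional_activity()] recovers).
#'
#' @param true_activities Numeric vector (>= 0), one per ORF.
#' @param lengths ORF lengths, bp.
#' @param bins Bin assignment, one per ORF.
#' @param depth Total reads to draw (>= 1).
#' @param seed Integer seed.
#' @param orf_ids Optional ORF names.
#' @return A [count_table] with the sampled counts and the renormalized
#'   `true_activity` column.
#' @export
generate_counts <- function(true_activities, lengths, bins, depth, seed = 1L,
                            orf_ids = NULL) {
  n <- length(true_activities)
  stopifnot(length(lengths) == n, length(bins) == n, all(true_activities >= 0),
            all(lengths > 0))
  if (depth < 1) stop("depth must be >= 1")
  if (is.null(orf_ids)) orf_ids <- sprintf("orf_%04d", seq_len(n))
  # canonicalize: length-weighted mean activity per bin = 1
  act <- true_activities
  for (b in unique(bins)) {
    i <- bins == b
    m <- sum(act[i] * lengths[i]) / sum(lengths[i])
    if (m > 0) act[i] <- act[i] / m
  }
  set.seed(as.integer(seed))
  prob <- act * lengths
  if (sum(prob) <= 0) stop("all activities are zero")
  counts <- as.integer(stats::rmultinom(1, size = depth, prob = prob))
  count_table(data.frame(orf_id = orf_ids, bin_id = bins, length = lengths,
                         count = counts, true_activity = act,
                         stringsAsFactors = FALSE))
}
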