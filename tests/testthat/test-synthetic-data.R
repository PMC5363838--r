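test_that("the simulator is a pure function of parameters and seed", {
  p <- chemostat_params()
  s1 <- simulate_cycle(p, n_cycles = 1)
  s2 <- simulate_cycle(p, n_cycles = 1)
  expect_identical(s1, s2)
  n1 <- simulate_cycle(p, n_cycles = 1, noise_sd = 0.05, seed = 3)
  n2 <- simulate_cycle(p, n_cycles = 1, noise_sd = 0.05, seed = 3)
  n3 <- simulate_cycle(p, n_cycles = 1, noise_sd = 0.05, seed = 4)
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
})

test_that("without biological activity oxygen decays as a closed-form exponential", {
  p <- chemostat_params(vmax = c(o2 = 0, no3 = 0, no2 = 0, n2o = 0, ferm = 0,
                                 cons = 0.35, s0 = 0, s0red = 0))
  sim <- simulate_cycle(p, n_cycles = 1, dt = 0.01)
  after <- sim[sim$time_h >= p$o2_pulse_min / 60, ]
  k <- p$strip[["O2"]] + p$med$dilution_rate / 24
  pred <- after$O2[1] * exp(-k * (after$time_h - after$time_h[1]))
  expect_lt(max(abs(after$O2 - pred)), 1e-6)
})

test_that("oxygen returns below 1 uM about two hours after the pulse", {
  sim <- simulate_cycle(chemostat_params(), n_cycles = 2)
  cyc <- sim[sim$time_h >= 12, ]                 # second (settled) cycle
  pulse_end <- 12 + chemostat_params()$o2_pulse_min / 60
  below <- cyc$time_h[cyc$time_h > pulse_end & cyc$O2 < 0.001]
  window <- min(below) - pulse_end
  expect_gt(window, 1.5)
  expect_lt(window, 2.5)
  # the pulse keeps dissolved O2 in the tens-of-micromolar regime
  expect_lt(max(sim$O2), 0.05)
})

test_that("trajectories stay non-negative and show the braided transients", {
  sim <- simulate_cycle(chemostat_params(), n_cycles = 2)
  traj <- sim[, c("O2", "NO2", "NO3", "N2O", "formate", "acetate",
                  "succinate", "S0", "biomass")]
  expect_true(all(traj >= -1e-9))
  cyc <- sim[sim$time_h >= 12, ]
  # N2O spikes while O2 is present (oxygen-sensitive N2O reductase)
  expect_gt(max(cyc$N2O), 2 * min(cyc$N2O))
  # S0 is produced during the oxic window and drawn down afterwards
  expect_gt(max(cyc$S0), min(cyc$S0))
})

test_that("the cumulative electron balance is recoverable from the trajectories", {
  p <- chemostat_params()
  sim <- simulate_cycle(p, n_cycles = 2, dt = 1 / 120)
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  D <- p$med$dilution_rate / 24
  pulse_h <- p$o2_pulse_min / 60
  o2in <- ifelse(sim$time_h %% p$period_h < pulse_h, p$o2_pulse_mM / pulse_h, 0)
  int_o2 <- trapz(sim$time_h, o2in) -
    trapz(sim$time_h, (p$strip[["O2"]] + D) * sim$O2) -
    (sim$O2[nrow(sim)] - sim$O2[1])
  int_no3 <- trapz(sim$time_h, p$med$concentrations[["NO3"]] * D - D * sim$NO3) -
    (sim$NO3[nrow(sim)] - sim$NO3[1])
  int_no2 <- trapz(sim$time_h, p$med$concentrations[["NO2"]] * D - D * sim$NO2) +
    int_no3 - (sim$NO2[nrow(sim)] - sim$NO2[1])
  int_n2o <- int_no2 / 2 - trapz(sim$time_h, p$strip[["N2O"]] * sim$N2O) -
    (sim$N2O[nrow(sim)] - sim$N2O[1])
  e_acc <- 4 * int_o2 + 2 * int_no3 + 3 * int_no2 + 2 * int_n2o
  model <- sim$e_accepted[nrow(sim)]
  # recomputation uses trapezoids on the output grid (the square O2 pulse
  # limits the attainable agreement), so compare at the percent level
  expect_lt(abs(e_acc - model) / model, 0.01)
  expect_equal(sim$delta_e, sim$e_donated - sim$e_accepted)
})

test_that("redox-tower mode suppresses denitrification while oxygen is present", {
  braided <- simulate_cycle(chemostat_params(), n_cycles = 1)
  sorted <- simulate_cycle(chemostat_params(redox_tower = TRUE), n_cycles = 1)
  # nitrite accumulates above its braided level when reduction is gated
  expect_gt(max(sorted$NO2), 2 * max(braided$NO2))
})

test_that("observation generation is exact without noise and seeded with it", {
  net <- default_network()
  vstar <- default_vstar()
  obs <- generate_observations(net, vstar)
  manual <- drop(stoich_matrix(net)[, names(vstar)] %*% vstar)
  expect_equal(obs$rates[names(manual)], manual)
  n1 <- generate_observations(net, vstar, noise_sd = 0.05, seed = 8)
  n2 <- generate_observations(net, vstar, noise_sd = 0.05, seed = 8)
  expect_identical(n1, n2)
  expect_error(generate_observations(net, c(bogus = 1)), "bogus")
})

test_that("multinomial counts recover the true activities at depth 1e6", {
  set.seed(31)
  n <- 60
  truth <- runif(n, 0.2, 3)
  lens <- sample(300:3000, n, replace = TRUE)
  bins <- rep(c("A", "B", "C"), each = n / 3)
  ct <- generate_counts(truth, lens, bins, depth = 1e6, seed = 12)
  act <- transcriptional_activity(ct)
  rmse <- sqrt(mean((act$activity - act$true_activity)^2))
  expect_lt(rmse, 0.05)
  # equal activities: expected counts proportional to length
  eq <- generate_counts(rep(1, n), lens, bins, depth = 1e6, seed = 13)
  expect_gt(stats::cor(eq$count, eq$length), 0.999)
  expect_error(generate_counts(truth, lens, bins, depth = 0), "depth")
})
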