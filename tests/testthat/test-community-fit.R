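test_that("a single-reaction network recovers a doubled rate exactly", {
  net <- toy_single_network()
  obs <- generate_observations(net, c(only = 2))
  fit <- fit_community(net, obs, scenario = "all", regularization = 1e-12)
  expect_equal(unname(fit$rates["only"]), 2, tolerance = 1e-8)
  expect_equal(community_yield(fit), net$reactions$only$yield_Y, tolerance = 1e-6)
})

test_that("noise-free observations are refit to machine-level accuracy", {
  net <- default_network()
  vstar <- default_vstar()
  obs <- generate_observations(net, vstar)
  fit <- fit_community(net, obs, "unsorted", regularization = 1e-10)
  truth <- predict(fit, vstar)
  expect_lt(max(abs(fit$modeled$rates - truth$rates[names(fit$modeled$rates)])),
            1e-6)
  expect_lt(max(abs(fit$rates[names(vstar)] - vstar)), 1e-5)
  expect_lt(max(abs(fit$rates[setdiff(names(fit$rates), names(vstar))])), 1e-5)
})

test_that("random sparse rate vectors with identifiable support are recovered", {
  net <- default_network()
  # the full unsorted network is deliberately redundant (several routes
  # share net conversions); supports drawn from one reaction per distinct
  # route leave the exact-fit solution unique
  pool <- c("d", "i", "o", "r", "t", "u", "v", "w", "x")
  set.seed(2024)
  for (i in 1:5) {
    support <- sample(pool, 5)
    vstar <- setNames(runif(length(support), 0.05, 2), support)
    obs <- generate_observations(net, vstar)
    fit <- fit_community(net, obs, "unsorted", regularization = 1e-10)
    expect_lt(max(abs(fit$rates[support] - vstar)), 1e-5)
  }
})

test_that("modeled conversions conserve carbon, nitrogen and electrons", {
  net <- default_network()
  fit <- fit_community(net, observed_conversions(), "unsorted")
  mod <- fit$modeled$rates
  cps <- net$compounds
  elements <- t(vapply(names(mod), function(id)
    c(cps[[id]]$composition, charge = cps[[id]]$charge), numeric(6)))
  totals <- drop(mod %*% elements)
  # water and protons are not tracked in the fit species, so only C, N and
  # the electron balance close exactly
  expect_lt(abs(totals[["C"]]), 1e-6)
  expect_lt(abs(totals[["N"]]), 1e-6)
  electrons <- sum(vapply(names(mod), function(id)
    mod[[id]] * electrons_per_mol(cps[[id]]), numeric(1)))
  expect_lt(abs(electrons), 1e-5)
})

test_that("the unsorted scenario matches the chemostat observations better", {
  net <- default_network()
  cmp <- scenario_compare(net, observed_conversions())
  expect_identical(cmp$best, "unsorted")
  expect_lt(cmp$fits$unsorted$residual_norm, cmp$fits$sorted$residual_norm)
  # the sorted scenario would have been more productive
  expect_gt(cmp$fits$sorted$community_yield, cmp$fits$unsorted$community_yield)
})

test_that("fermenter bins grow only in the unsorted scenario", {
  net <- default_network()
  obs <- observed_conversions()
  ab_un <- population_abundances(fit_community(net, obs, "unsorted"))
  ab_so <- population_abundances(fit_community(net, obs, "sorted"))
  expect_gt(ab_un[["D"]] + ab_un[["F"]], 0)
  expect_true(!any(c("D", "F") %in% names(ab_so)) ||
                all(ab_so[intersect(c("D", "F"), names(ab_so))] == 0))
  expect_equal(sum(ab_un), 1, tolerance = 1e-9)
})

test_that("pure canonical-respiration observations fit the sorted scenario", {
  net <- default_network()
  obs <- generate_observations(net, c(a = 0.5, b = 1.0, c = 0.2))
  fit <- fit_community(net, obs, "sorted", regularization = 1e-10)
  expect_lt(fit$residual_norm, 1e-5)
  expect_equal(unname(fit$rates[c("a", "b", "c")]), c(0.5, 1.0, 0.2),
               tolerance = 1e-4)
})

test_that("identical allowed sets give identical results", {
  net <- toy_two_bin_network()    # all reactions tagged 'both'
  obs <- generate_observations(net, c(p1 = 1, q1 = 2))
  f1 <- fit_community(net, obs, "sorted")
  f2 <- fit_community(net, obs, "unsorted")
  expect_equal(f1$rates, f2$rates)
  expect_equal(f1$community_yield, f2$community_yield)
})

test_that("population abundances are growth shares excluding storage", {
  net <- toy_two_bin_network()
  # rates chosen so biomass production of P:Q is 1:3
  xp <- net$reactions$p1$net_stoich[["biomass"]]
  xq <- net$reactions$q1$net_stoich[["biomass"]]
  obs <- generate_observations(net, c(p1 = 1, q1 = 3 * xp / xq))
  fit <- fit_community(net, obs, "all", regularization = 1e-12)
  ab <- population_abundances(fit)
  expect_equal(unname(ab[c("P", "Q")]), c(0.25, 0.75), tolerance = 1e-6)

  only <- fit_community(net, generate_observations(net, c(p1 = 1)), "all",
                        regularization = 1e-12)
  expect_equal(unname(population_abundances(only)["P"]), 1, tolerance = 1e-6)
})

test_that("degenerate inputs are handled explicitly", {
  net <- toy_single_network()
  zero <- conversion_vector(c(glucose = 0, O2 = 0, CO2 = 0))
  expect_warning(fit <- fit_community(net, zero), "zero")
  expect_true(all(fit$rates == 0))
  expect_error(community_yield(fit), "consumption")
  expect_error(population_abundances(fit), "grows")
  expect_error(fit_community(net, conversion_vector(c(N2O = 1))), "no species")
})

test_that("5% observation noise moves the community yield by < 0.05", {
  net <- default_network()
  obs0 <- observed_conversions()
  y0 <- fit_community(net, obs0, "unsorted")$community_yield
  set.seed(42)
  for (i in 1:4) {
    r <- obs0$rates
    nz <- r != 0
    r[nz] <- r[nz] * (1 + stats::rnorm(sum(nz), 0, 0.05))
    y <- fit_community(net, conversion_vector(r), "unsorted")$community_yield
    expect_lt(abs(y - y0), 0.05)
  }
})

test_that("fit methods expose rates, fitted values and residuals", {
  net <- default_network()
  obs <- observed_conversions()
  fit <- fit_community(net, obs, "unsorted")
  expect_identical(coef(fit), fit$rates)
  expect_s3_class(fitted(fit), "conversion_vector")
  res <- residuals(fit)
  expect_true(all(names(res) %in% names(obs$rates)))
  expect_equal(unname(res["glucose"]), 0, tolerance = 1e-6)
  out <- utils::capture.output(print(summary(fit)))
  expect_true(any(grepl("community yield", out)))
})
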