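ctx <- energy_context()
glc_cat <- half_reaction(c(glucose = -1, O2 = -6, CO2 = 6, H2O = 6))

test_that("dissipation correlation reproduces its closed form", {
  # frozen from independent hand evaluation of the closed form
  expect_equal(dissipation_correlation(6, 4), 236.05, tolerance = 1e-4)
  expect_equal(dissipation_correlation(2, 4), 432.12, tolerance = 1e-4)
  # C1 substrates dissipate more than C6 at equal reduction
  expect_gt(dissipation_correlation(1, 4), dissipation_correlation(6, 4))
  expect_error(dissipation_correlation(0, 4), ">= 1")
  expect_error(dissipation_correlation(2, 0), "positive")
})

test_that("reaction Gibbs energies sum formation energies", {
  # identity conversion (empty net stoichiometry) has zero Gibbs energy
  expect_equal(reaction_gibbs(half_reaction(c(glucose = 0, CO2 = 0)), ctx), 0)
  # hand-summed once from the shipped table: -2872.02 kJ/mol glucose
  expect_equal(reaction_gibbs(glc_cat, ctx), -2872.02, tolerance = 1e-6)
  rev <- half_reaction(-glc_cat$stoich)
  expect_equal(reaction_gibbs(rev, ctx), -reaction_gibbs(glc_cat, ctx))
  expect_error(reaction_gibbs(half_reaction(c(unknownium = -1, CO2 = 1),
    compounds = c(default_compounds(),
                  list(unknownium = compound("unknownium", "CH4")))), ctx),
    "unknownium")
})

test_that("anabolic halves produce exactly 1 C-mol biomass and balance", {
  for (sub in c("glucose", "acetate", "formate", "succinate", "alanine",
                "glutamate", "methionine")) {
    an <- anabolic_half(sub)
    expect_identical(nrow(check_balance(an)), 0L)
    expect_equal(unname(an$stoich["biomass"]), 1)
  }
  # electron bookkeeping: glucose anabolism consumes 1.05 C-mol per C-mol X
  an <- anabolic_half("glucose")
  expect_equal(unname(-an$stoich["glucose"] * 6), 1.05)
})

test_that("coupling reproduces the literature yield anchors", {
  aerobic <- couple_halves(glc_cat, "glucose", ctx, chain = "canonical")
  expect_equal(aerobic$yield_Y, 0.7, tolerance = 0.15)   # ~0.62 in [0.6, 0.8]
  expect_true(aerobic$yield_Y >= 0.6 && aerobic$yield_Y < 0.8)

  denit_cat <- half_reaction(balance_skeleton(c(acetate = -1, NO2 = -8/3, N2 = 4/3)))
  denit <- couple_halves(denit_cat, "acetate", ctx, chain = "denitrification")
  expect_equal(denit$yield_Y, 0.30, tolerance = 0.05 / 0.30)
  expect_true(abs(denit$yield_Y - 0.30) < 0.05)

  expect_identical(nrow(check_balance(aerobic)), 0L)
  expect_identical(nrow(check_balance(denit)), 0L)
})

test_that("yield vanishes as the dissipation demand grows", {
  ys <- vapply(c(236, 1e3, 1e4, 1e6), function(d) {
    cx <- energy_context(dissipation_override = d)
    couple_halves(glc_cat, "glucose", cx)$yield_Y
  }, numeric(1))
  expect_true(all(diff(ys) < 0))      # monotone decreasing in dissipation
  expect_lt(ys[length(ys)], 1e-3)     # burn-everything limit
})

test_that("aerobic >= denitrifying >= fermentative yield on glucose", {
  aerob <- couple_halves(glc_cat, "glucose", ctx, chain = "canonical")$yield_Y
  den_cat <- half_reaction(balance_skeleton(c(glucose = -1, NO2 = -8, N2 = 4)))
  denit <- couple_halves(den_cat, "glucose", ctx, chain = "denitrification")$yield_Y
  ferm_cat <- half_reaction(balance_skeleton(
    c(glucose = -1, formate = 2, acetate = 2, H2 = 2)))
  ferm <- couple_halves(ferm_cat, "glucose", ctx)$yield_Y
  expect_gte(aerob, denit)
  expect_gte(denit, ferm)
})

test_that("endergonic catabolic halves are rejected", {
  uphill <- half_reaction(c(CO2 = -6, H2O = -6, glucose = 1, O2 = 6))
  expect_error(couple_halves(uphill, "glucose", ctx), "not a catabolism")
})

test_that("the yield report tabulates every reaction", {
  net <- default_network()
  rep <- yield_report(net$reactions)
  expect_identical(nrow(rep), length(net$reactions))
  expect_true(all(rep$yield_Y >= 0 & rep$yield_Y < 1))
})
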