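test_that("degree of reduction follows the conventional valence bookkeeping", {
  cps <- default_compounds()
  expect_equal(degree_of_reduction(compound("glc", "C6H12O6")), 4)
  # acetate as acetic acid and as the anion give the same gamma
  expect_equal(degree_of_reduction(compound("hac", "C2H4O2")), 4)
  expect_equal(degree_of_reduction(cps$acetate), 4)
  expect_equal(degree_of_reduction(compound("ch4", "CH4")), 8)
  expect_equal(degree_of_reduction(cps$CO2), 0)
  expect_equal(degree_of_reduction(cps$biomass), 4.2, tolerance = 0.01)
  expect_error(degree_of_reduction(cps$O2), "C0")
})

test_that("element and charge balance is checked to 1e-9", {
  combustion <- half_reaction(c(glucose = -1, O2 = -6, CO2 = 6, H2O = 6))
  expect_identical(nrow(check_balance(combustion)), 0L)

  broken <- half_reaction(c(glucose = -1, O2 = -5, CO2 = 6, H2O = 6))
  viol <- check_balance(broken)
  expect_identical(viol$element, "O")
  expect_equal(viol$imbalance, 2)

  # hand-balanced nitrite denitrification of formaldehyde-level carbon:
  # 4 NO2- + 3 CH2O + 4 H+ -> 2 N2 + 3 CO2 + 5 H2O
  cps <- c(default_compounds(), list(CH2O = compound("CH2O", "CH2O")))
  r <- half_reaction(c(NO2 = -4, CH2O = -3, H = -4, N2 = 2, CO2 = 3, H2O = 5),
                     compounds = cps)
  expect_identical(nrow(check_balance(r, cps)), 0L)

  expect_error(check_balance(c(unobtainium = -1)), "unobtainium")
})

test_that("balance_skeleton completes reactions exactly", {
  st <- balance_skeleton(c(glucose = -1, O2 = -6))
  expect_equal(unname(st[c("CO2", "H2O")]), c(6, 6))
  expect_identical(nrow(check_balance(st)), 0L)
  # amino-acid oxidation releases ammonium
  st2 <- balance_skeleton(c(alanine = -1, O2 = -3))
  expect_equal(unname(st2["NH4"]), 1)
  expect_identical(nrow(check_balance(st2)), 0L)
  expect_error(balance_skeleton(c(methionine = -1, O2 = -5.5)), "balanced")
})

test_that("carbon fractions of the supplied medium match the printed shares", {
  med <- default_medium()
  fr <- carbon_fractions(med)
  # hand-summed C-mol: glucose 36 mM of 67.16 mM total; acetate 6.2
  expect_equal(unname(fr["glucose"]), 36 / 67.16, tolerance = 1e-10)
  expect_equal(unname(fr["acetate"]), 6.2 / 67.16, tolerance = 1e-10)
  expect_equal(sum(fr), 1, tolerance = 1e-12)

  grouped <- carbon_fractions(med, grouping = c(
    glutamate = "aa", aspartate = "aa", alanine = "aa", serine = "aa",
    tyrosine = "aa", histidine = "aa", methionine = "aa"))
  expect_equal(unname(grouped["aa"]), 24.96 / 67.16, tolerance = 1e-10)

  expect_equal(unname(carbon_fractions(medium(c(glucose = 2), 0.3))), 1)
  expect_error(carbon_fractions(medium(c(NO2 = 20), 0.26)), "no carbon")
})

test_that("carbon fractions sum to one for random media", {
  ids <- c("glucose", "acetate", "alanine", "serine", "formate", "NO2")
  set.seed(101)
  for (i in 1:20) {
    conc <- setNames(runif(length(ids), 0.01, 10), ids)
    fr <- carbon_fractions(medium(conc, runif(1, 0.05, 2)))
    expect_equal(sum(fr), 1, tolerance = 1e-12)
  }
})

test_that("supply rates are concentration times dilution rate", {
  sup <- supply_rates(default_medium())$rates
  expect_equal(unname(sup["NO2"]), 5.2)
  expect_equal(unname(sup["glucose"]), 1.56)
  empty <- supply_rates(medium(setNames(numeric(0), character(0)), 0.26))
  expect_identical(length(empty$rates), 0L)
})

test_that("generation count is duration * D / ln 2", {
  expect_equal(generations(100, 0.26), 37.51, tolerance = 0.01)
  # one doubling time gives exactly one generation
  expect_equal(generations(log(2) / 0.26, 0.26), 1)
  expect_equal(generations(50, 0.26), 18.755, tolerance = 0.01)
  expect_error(generations(-1, 0.26), "positive")
  expect_error(generations(10, 0), "positive")
})

test_that("formula parsing handles fractional and multi-element formulas", {
  x <- parse_formula("CH1.8O0.5N0.2")
  expect_equal(unname(x[c("C", "H", "O", "N")]), c(1, 1.8, 0.5, 0.2))
  expect_equal(unname(parse_formula("C5H11NO2S")["S"]), 1)
  expect_error(parse_formula("C6Xq2"), "parse|element")
})
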