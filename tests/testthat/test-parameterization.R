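test_that("diffusion-limited association rate follows the closed form", {
  expect_equal(diffusionLimitedRate(0.01, 1, 4), 4 * pi * 0.01 / 4)
  expect_equal(signif(diffusionLimitedRate(0.01, 1, 4), 1), 0.03)
  expect_equal(diffusionLimitedRate(0.01, 2, 4), 0.0628, tolerance = 1e-2)
  expect_lt(diffusionLimitedRate(1e-9, 1, 4), 1e-8)
  expect_error(diffusionLimitedRate(-0.01, 1, 4), "positive")
})

test_that("mean-lifetime convention gives 1/tau, not ln2/tau", {
  expect_equal(rateFromMeanLifetime(1200), 1 / 1200)
  expect_equal(signif(rateFromMeanLifetime(1200), 2), 0.00083)
  expect_equal(rateFromMeanLifetime(3600), 2.78e-4, tolerance = 1e-3)
  expect_lt(rateFromMeanLifetime(1e12), 1e-11)
  expect_error(rateFromMeanLifetime(0), "positive")
})

test_that("binding equilibrium matches a damped fixed-point oracle", {
  cases <- list(c(bO = 100, bT = 100), c(bO = 0.1, bT = 100),
                c(bO = 10, bT = 10))
  for (cs in cases) {
    p <- paramSet(c(fO = 0.03, cs), NT = 500)
    eq <- solveBindingEquilibrium(900, p, "noncoop")
    or <- bindingEquilibriumOracle(900, 0.03, cs[["bO"]], cs[["bT"]], 500)
    expect_equal(eq$C_free, or$C_free, tolerance = 1e-6)
    expect_equal(eq$theta_O, or$theta_O, tolerance = 1e-6)
  }
  # reference values of the two published regimes
  pu <- paramSet(fO = 0.03, bO = 100, bT = 100, NT = 500)
  equ <- solveBindingEquilibrium(900, pu, "noncoop")
  expect_equal(equ$C_free, 803, tolerance = 2e-3)
  expect_equal(equ$theta_O, 0.194, tolerance = 5e-3)
  ps <- paramSet(fO = 0.03, bO = 0.1, bT = 100, NT = 500)
  expect_equal(solveBindingEquilibrium(900, ps, "noncoop")$theta_O,
               0.996, tolerance = 1e-3)
})

test_that("binding equilibrium limits: infinitely weak binding frees everything", {
  p <- paramSet(fO = 0.03, bO = 1e12, bT = 1e12, NT = 500)
  eq <- solveBindingEquilibrium(900, p, "noncoop")
  expect_equal(eq$C_free, 900, tolerance = 1e-6)
  expect_lt(eq$theta_O, 1e-8)
})

test_that("expression-rate derivation reproduces the published tables to 2%", {
  obs <- observableSet()
  pu <- paramSet(fO = 0.03, bO = 100, bT = 100, NT = 500)
  exu <- deriveExpressionRates(obs, solveBindingEquilibrium(900, pu, "noncoop"),
                               fC_given = 0.0274)
  expect_equal(exu$fM, 0.0302, tolerance = 0.02)
  expect_equal(exu$bC, 0.00024, tolerance = 0.02)
  ps <- paramSet(fO = 0.03, bO = 0.1, bT = 100, NT = 500)
  exs <- deriveExpressionRates(obs, solveBindingEquilibrium(900, ps, "noncoop"),
                               fC_given = 0.0261)
  expect_equal(exs$fM, 0.0059, tolerance = 0.02)
  expect_equal(exs$bC, 0.00023, tolerance = 0.02)
  # fully occupied promoter: transcription balances decay directly
  eq1 <- list(theta_productive = 1, C_free = 800)
  expect_equal(deriveExpressionRates(obs, eq1, 0.027)$fM, (1 / 1200) * 7)
  eq0 <- list(theta_productive = 0, C_free = 800)
  expect_error(deriveExpressionRates(obs, eq0, 0.027), "occupancy")
})

test_that("derived rates close the loop: the ON state returns the observables", {
  obs <- observableSet()
  for (binding in list(c(bO = 100, bT = 100), c(bO = 0.1, bT = 100))) {
    ps <- deriveParams(obs, binding = binding, fC_given = 0.0274)
    ss <- steadyStateObservables(ps, "noncoop")
    expect_equal(ss$M_ss, obs$M_ss, tolerance = 0.01)
    expect_equal(ss$C_total, obs$C_total, tolerance = 0.01)
  }
})

test_that("photobleach-recovery calibration round-trips a known rate pair", {
  obs <- observableSet()
  p <- publishedParams("stable4B")
  truth <- c(fC = 0.0261, bC = 0.00023)
  ht <- SelectorSwitch:::frapHalfTimeDeterministic(p, obs, truth[["fC"]],
                                                   truth[["bC"]], "noncoop", 0.8)
  cal <- calibrateProteinRatesToFrap(p, obs, target_half_life = ht)
  expect_equal(cal$bC, truth[["bC"]], tolerance = 0.01)
  expect_equal(cal$fC, truth[["fC"]], tolerance = 0.01)
  expect_equal(cal$achieved_half_life, ht, tolerance = 0.01)
  expect_error(calibrateProteinRatesToFrap(p, obs, target_half_life = 1),
               "binding-limited|shorter")
})

test_that("system-size scaling preserves occupancies and scales copy numbers", {
  ps <- publishedParams("unstable4B")
  sc <- scaleParams(ps, 10)
  ss <- steadyStateObservables(ps, "noncoop")
  ssc <- steadyStateObservables(sc, "noncoop")
  expect_equal(ssc$theta_O, ss$theta_O, tolerance = 0.02)
  expect_equal(ssc$C_total, ss$C_total / 10, tolerance = 0.02)
  expect_equal(ssc$M_ss, ss$M_ss / 10, tolerance = 0.02)
  expect_equal(sc@NT, 50)
})
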