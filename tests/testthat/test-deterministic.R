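test_that("the rate equations vanish at fixed points and conserve promoters", {
  ps <- publishedParams("unstable4B")
  for (fp in findFixedPoints(ps, "noncoop"))
    expect_lt(max(abs(odeRhs(fp$state, ps, "noncoop"))), 1e-8)
  # promoter-ledger derivatives vanish at arbitrary states, every variant
  configs <- list(noncoop = publishedParams("stable4E"),
                  coop = paramSet(fO = 0.03, b1 = 1, b2 = 1, bT = 100,
                                  fM = 0.03, bM = 1e-3, fC = 0.027,
                                  bC = 2e-4, NT = 500),
                  hd1b = publishedParams("hd1b"), hd2b = publishedParams("hd2b"))
  set.seed(4)
  for (nm in names(configs)) {
    v <- if (nm == "noncoop") "noncoop" else nm
    net <- buildNetwork(v, configs[[nm]])
    for (rep in 1:3) {
      st <- setNames(runif(length(net@species), 0, 50), net@species)
      d <- odeRhs(st, configs[[nm]], v)
      for (grp in SelectorSwitch:::promoterLedgers(net@species))
        expect_lt(abs(sum(d[grp])), 1e-9)
    }
  }
})

test_that("fixed-point structure: monostable-with-threshold vs true bistability", {
  # monomer binding: ON point plus a half-stable boundary at the origin
  fn <- findFixedPoints(publishedParams("unstable4B"), "noncoop")
  expect_length(fn, 2)
  expect_setequal(vapply(fn, `[[`, "", "stability"),
                  c("half-stable", "stable"))
  # dimer binding: three fixed points, two stable flanking one unstable
  pc <- paramSet(fO = 0.03, b1 = 1, b2 = 1, bT = 100, fM = 0.0302,
                 bM = 1 / 1200, fC = 0.0274, bC = 0.00024, NT = 500)
  fc <- findFixedPoints(pc, "coop")
  expect_length(fc, 3)
  expect_equal(vapply(fc[order(vapply(fc, `[[`, 0, "C_free"))],
                      `[[`, "", "stability"),
               c("stable", "unstable", "stable"))
  # no transcription at all: only the origin remains
  p0 <- setRates(publishedParams("unstable4B"), fM = 0)
  f0 <- findFixedPoints(p0, "noncoop")
  expect_length(f0, 1)
  expect_equal(f0[[1]]$C_free, 0)
})

test_that("bistability persists over part of the cooperative dissociation grid", {
  grid <- expand.grid(b = c(0.1, 1, 10), bT = c(10, 100))
  nfp <- mapply(function(b, bT) {
    pc <- paramSet(fO = 0.03, b1 = b, b2 = b, bT = bT, fM = 0.0302,
                   bM = 1 / 1200, fC = 0.0274, bC = 0.00024, NT = 500)
    length(findFixedPoints(pc, "coop"))
  }, grid$b, grid$bT)
  expect_true(any(nfp == 3))
})

test_that("steady-state observables match the published operating points", {
  ss <- steadyStateObservables(publishedParams("unstable4B"), "noncoop")
  expect_equal(round(ss$M_ss), 7)
  expect_equal(signif(ss$C_total, 2), 900)
  ssDep <- steadyStateObservables(publishedParams("stable4E"), "noncoop")
  expect_equal(signif(ssDep$C_total, 1), 100)
  # constant overrides give the perturbed quasi-steady state
  ssOv <- steadyStateObservables(publishedParams("stable4B"), "noncoop",
                                 overrides = c(bC = 0.0019, fC = 0.024))
  expect_equal(signif(ssOv$C_total, 1), 100)
})

test_that("stable fixed points attract perturbed trajectories", {
  ps <- publishedParams("unstable4B")
  on <- steadyStateObservables(ps, "noncoop")
  net <- buildNetwork("noncoop", ps)
  st0 <- SelectorSwitch:::onStateVector(net, ps, continuous = TRUE)
  st0["C"] <- st0["C"] * 0.6
  st0["M"] <- st0["M"] * 2
  sol <- deterministicTrajectory(ps, "noncoop", times = c(0, 5e4, 2e5),
                                 state0 = st0)
  final <- sol[nrow(sol), -1]
  w <- SelectorSwitch:::che1Weights(net@species)
  expect_equal(unname(sum(final * w)), on$C_total, tolerance = 1e-3)
})

test_that("ensemble mean of the jump process tracks the rate equations", {
  # mean-field agreement holds at large copy numbers; start the ODE and
  # the ensemble from the same displaced integer state
  ps <- publishedParams("unstable4B")
  net <- buildNetwork("noncoop", ps)
  times <- seq(0, 1200, by = 300)
  st0 <- SelectorSwitch:::onStateVector(net, ps)
  st0["C"] <- round(st0["C"] * 0.5)
  ode <- deterministicTrajectory(ps, "noncoop", times = times, state0 = st0)
  runs <- vapply(1:40, function(i) {
    tr <- gillespieRun(net, ps, init = st0, tMax = max(times), seed = 800 + i,
                       sampleDt = 300)
    tr@states[, "C"]
  }, numeric(length(times)))
  mC <- rowMeans(runs)
  seC <- apply(runs, 1, sd) / sqrt(ncol(runs))
  # 3 SE plus a small mean-field slack (promoter-state correlations)
  expect_true(all(abs(mC - ode[, "C"]) <= 3 * seC + 0.02 * ode[, "C"]))
})

test_that("the Poisson switching bound follows the stated formula", {
  expect_equal(requiredOnLifetime(1 - exp(-1), 1000)$bound, 1000)
  expect_equal(requiredOnLifetime(1e-6, 14 * 86400)$bound_years,
               3.8e4, tolerance = 0.02)
  expect_gt(requiredOnLifetime(1e-12, 1000)$bound, 1e14)
  expect_equal(requiredOnLifetime(1e-6, 1000)$approx, 1e9)
  expect_error(requiredOnLifetime(0, 100), "phi")
  expect_error(requiredOnLifetime(0.5, -1), "positive")
})
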