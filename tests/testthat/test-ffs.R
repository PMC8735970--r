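# quickly relaxing metastable switch (depletion-phase turnover rates):
# its basin decorrelates in ~1/bC ~ 500 s, so short pilots already give
# meaningful moments
fastBasinParams <- function() {
  paramSet(fO = 0.03, bO = 0.1, bT = 100, fM = 0.0059, bM = 1 / 1200,
           fC = 0.024, bC = 0.0019, NT = 500)
}

test_that("interface placement respects count, ordering and the basin", {
  ps <- fastBasinParams()
  cfg <- suppressMessages(placeInterfaces(ps, "noncoop", trials = 50,
                                          maxStore = 20, seed = 5,
                                          tPilot = 20000))
  n <- length(cfg@interfaces)
  expect_gte(n, 20)
  expect_lte(n, 35)
  expect_true(all(diff(cfg@interfaces) < 0))
  expect_equal(tail(cfg@interfaces, 1), 0)
  expect_gt(cfg@lambdaA, cfg@interfaces[1])
  expect_lt(cfg@interfaces[1], cfg@lambdaOn)
  # a step as large as the basin mean cannot define a ladder
  expect_error(placeInterfaces(ps, "noncoop", step = 1e4, seed = 5,
                               tPilot = 3000), "step")
})

test_that("pilot-based first-interface placement is stable across seeds", {
  # the first interface tracks the basin median, whose pilot-to-pilot
  # sampling error is set by the slow protein mode; placements from
  # independent pilots agree within a couple of basin spreads
  ps <- fastBasinParams()
  basin <- characterizeOnBasin(ps, "noncoop", tSample = 20000, seed = 5)
  l0 <- vapply(c(5, 6), function(s)
    suppressMessages(placeInterfaces(ps, "noncoop", trials = 50, seed = s,
                                     tPilot = 20000))@interfaces[1], 0)
  expect_lte(abs(diff(l0)), 2.5 * basin$lambdaRobustSd)
})

test_that("the lifetime formula collapses to 1/flux when every stage succeeds", {
  cfg <- new("FFSConfig", lambdaOn = 100, lambdaA = 91, interfaces = c(90, 45, 0),
             trials = 10, maxStore = 10, seed = 1)
  res <- new("FFSResult", config = cfg, flux0 = 0.02, nCross0 = 50,
             p = c(1, 1), pErr = c(0, 0), lifetime = 1 / (0.02 * 1 * 1),
             lifetimeLogSE = 0.1, lowerBoundOnly = FALSE, paths = list(),
             species = "C")
  expect_equal(res@lifetime, 1 / res@flux0)
})

test_that("flux sampling agrees with brute-force first passage", {
  ps <- tinyUnstable()
  # brute-force oracle: independent seeds, plain first-passage ensemble
  fpt <- vapply(1:14, function(s)
    firstPassageToOff(ps, "noncoop", seed = 5000 + s, tMax = 2e6)$time, 0)
  expect_true(all(!is.na(fpt)))
  mfpt <- mean(fpt)
  seB <- sd(fpt) / sqrt(length(fpt))
  cfg <- placeInterfaces(ps, "noncoop", trials = 150, maxStore = 50,
                         seed = 21, tPilot = 6000)
  res <- ffsRun(ps, "noncoop", cfg, maxCross0 = 30)
  expect_false(res@lowerBoundOnly)
  expect_true(all(res@p >= 0 & res@p <= 1, na.rm = TRUE))
  seF <- res@lifetime * res@lifetimeLogSE
  expect_lt(abs(res@lifetime - mfpt), 2 * sqrt(seB^2 + seF^2))
})

test_that("lifetimes grow when the selector holds its own promoter longer", {
  # 3-point monotonicity in the own-promoter dissociation rate at 1/10
  # copy numbers; the ordering spans two orders of magnitude, far beyond
  # the estimator error
  obs <- observableSet()
  lt <- vapply(c(1, 10, 100), function(bO) {
    ps <- deriveParams(obs, binding = c(bO = bO, bT = 10),
                       fC_given = 0.0274)
    ps <- scaleParams(ps, 10)
    cfg <- placeInterfaces(ps, "noncoop", trials = 70, maxStore = 30,
                           seed = 31, tPilot = 10000)
    ffsRun(ps, "noncoop", cfg, maxCross0 = 15)@lifetime
  }, 0)
  expect_gt(lt[1], lt[2])
  expect_gt(lt[2], lt[3])
})

test_that("a single harvested path averages to its own profile", {
  cfg <- new("FFSConfig", lambdaOn = 40, lambdaA = 31, interfaces = c(30, 15, 0),
             trials = 10, maxStore = 10, seed = 1)
  path <- cbind(t = c(0, 1, 2, 3),
                O = c(0, 0, 1, 1), OC = c(1, 1, 0, 0),
                OTf = c(8, 9, 10, 10), OTC = c(2, 1, 0, 0),
                M = c(1, 1, 0, 0), C = c(20, 10, 4, 0))
  res <- new("FFSResult", config = cfg, flux0 = 0.01, nCross0 = 10,
             p = c(0.5, 0.5), pErr = c(0.1, 0.1), lifetime = 400,
             lifetimeLogSE = 0.2, lowerBoundOnly = FALSE,
             paths = list(path),
             species = c("O", "OC", "OTf", "OTC", "M", "C"))
  # C_total per row: 23, 12, 4, 0 -> bins (0,12] x3 (rows 2-4) and (12,30] x1
  prof <- averageTransitionPath(res, breaks = c(0, 12, 30))
  expect_equal(prof$theta_own, c(1 / 3, 1))
  expect_equal(prof$target_occ, c(0.1 / 3, 0.2))
  expect_equal(prof$nObs, c(3, 1))
  expect_error(averageTransitionPath(new("FFSResult", config = cfg,
    flux0 = 1, nCross0 = 1, p = 1, pErr = 0, lifetime = 1,
    lifetimeLogSE = 0, lowerBoundOnly = FALSE, paths = list(),
    species = "C")), "path")
})
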