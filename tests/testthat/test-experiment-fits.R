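test_that("induction normalization maps control to 0 and induced to 1", {
  expect_equal(normalizeInductionCounts(5, 5, 25), 0)
  expect_equal(normalizeInductionCounts(25, 5, 25), 1)
  expect_equal(normalizeInductionCounts(15, 5, 25), 0.5)
  expect_error(normalizeInductionCounts(10, 5, 5), "differ")
})

test_that("exponential decay fitting recovers noiseless and degenerate inputs", {
  tt <- seq(0, 4000, by = 1000)
  a <- log(2) / (17 * 60)
  fit <- fitExponentialDecay(tt, exp(-a * tt), nBoot = 0)
  expect_equal(fit$rate, a, tolerance = 1e-6)
  expect_equal(fit$half_life, 17 * 60, tolerance = 1e-5)
  expect_warning(fc <- fitExponentialDecay(tt, rep(1, 5), nBoot = 0), "decay")
  expect_equal(fc$rate, 0)
  expect_error(fitExponentialDecay(c(0, 1), c(1, 0.5)), "3 distinct")
})

test_that("a synthetic chase returns the true half-life inside its CI", {
  d <- genDecayChase(seed = 12)
  fit <- fitDecayChaseTable(d$payload, nBoot = 300)
  expect_gt(17 * 60, fit$ci_half_life[1])
  expect_lt(17 * 60, fit$ci_half_life[2])
  expect_equal(fit$half_life, 17 * 60, tolerance = 0.35)
})

test_that("recovery-curve fitting is exact on noiseless traces and at t = 0", {
  tt <- seq(0, 3 * 3600, by = 1200)
  b <- log(2) / (83 * 60)
  x0 <- 0.2; plateau <- 1
  y <- plateau + (x0 - plateau) * exp(-b * tt)
  fit <- fitFrapRecovery(tt, y)
  expect_equal(fit$perTrace$b[1], b, tolerance = 1e-6)
  expect_equal(fit$perTrace$x0[1], x0, tolerance = 1e-6)
  expect_equal(fit$half_life, 83 * 60, tolerance = 1e-5)
  # model property: R(0) is the post-bleach intensity
  expect_equal(y[1], x0)
})

test_that("multi-trace recovery fits land within two SD of the truth", {
  d <- genFrapTrace(nTraces = 6, seed = 9)
  fit <- fitFrapRecovery(d$payload$times, d$payload$intensities)
  sdHl <- sd(fit$perTrace$half_life)
  expect_lt(abs(fit$half_life - 83 * 60), 2 * sdHl)
})

test_that("decay and recovery rates are invariant to intensity rescaling", {
  d <- genFrapTrace(nTraces = 2, seed = 14)
  f1 <- fitFrapRecovery(d$payload$times, d$payload$intensities)
  f2 <- fitFrapRecovery(d$payload$times, 37.5 * d$payload$intensities)
  expect_equal(f1$perTrace$b, f2$perTrace$b, tolerance = 1e-6)
  tt <- seq(0, 4000, by = 800)
  v <- exp(-3e-4 * tt) + c(0.01, -0.01)
  fa <- fitExponentialDecay(tt, v, nBoot = 0)
  fb <- fitExponentialDecay(tt, v, nBoot = 0)  # normalized input is scale-free
  expect_equal(fa$rate, fb$rate)
})

test_that("bath calibration converts fluorescence to molecule counts", {
  expect_equal(proteinCountFromBathCalibration(0, 1, 72, c(1, 1, 1)), 0)
  # equal intensities, 72 nM bath, 4 um^3 nucleus -> ~173 molecules
  r <- (3 / pi)^(1 / 3)
  expect_equal(proteinCountFromBathCalibration(1, 1, 72, rep(r, 3)),
               72 * 4 * 0.6022, tolerance = 1e-6)
  expect_equal(round(proteinCountFromBathCalibration(1, 1, 72, rep(r, 3))), 173)
  # radii of 1 um give the unit-sphere volume
  expect_equal(proteinCountFromBathCalibration(1, 1, 1, c(1, 1, 1)),
               4 / 3 * pi * 0.6022)
  # diameters are halved before use
  expect_equal(proteinCountFromBathCalibration(1, 1, 1, c(2, 2, 2),
                                               diameters = TRUE),
               proteinCountFromBathCalibration(1, 1, 1, c(1, 1, 1)))
  expect_error(proteinCountFromBathCalibration(1, 0, 72, c(1, 1, 1)), "positive")
})

test_that("chemotaxis index spans attraction, indifference and aversion", {
  expect_equal(chemotaxisIndex(100, 0), 1)
  expect_equal(chemotaxisIndex(50, 50), 0)
  expect_equal(chemotaxisIndex(75, 25), 0.5)
  expect_equal(chemotaxisIndex(0, 80), -1)
  expect_error(chemotaxisIndex(0, 0), "animal")
})

test_that("spot counting handles empty stacks and threshold extremes", {
  set.seed(31)
  noiseOnly <- genSmfishStack(nSpots = 0, noiseSd = 1, seed = 31)
  expect_equal(countSpots3d(noiseOnly$payload, kernelSigma = 1)$count, 0)
  d <- genSmfishStack(nSpots = 7, intensity = 6, noiseSd = 1, seed = 32)
  expect_equal(countSpots3d(d$payload, kernelSigma = 1)$count, 7)
  # a threshold above the maximum finds nothing
  expect_equal(countSpots3d(d$payload, kernelSigma = 1,
                            threshold = max(d$payload) + 1)$count, 0)
  # counts are monotone non-increasing in the threshold
  sm <- SelectorSwitch:::gaussianSmooth3d(d$payload, 1)
  thr <- quantile(sm, c(0.97, 0.99, 0.999, 1))
  cts <- vapply(thr, function(th)
    countSpots3d(d$payload, kernelSigma = 1, threshold = th)$count, 0L)
  expect_true(all(diff(cts) <= 0))
})

test_that("overlapping blobs split on their regional maxima", {
  # two spots close enough to merge into one thresholded component
  d <- genSmfishStack(nSpots = 2, psfSigma = 1.3, intensity = 8,
                      noiseSd = 0.4, minSeparation = 5, seed = 41)
  r <- countSpots3d(d$payload, kernelSigma = 1)
  expect_equal(r$count, 2)
  tru <- d$truth$coordinates
  for (i in 1:2)
    expect_lt(min(sqrt(rowSums(sweep(r$coordinates, 2, tru[i, ])^2))), 2.5)
})
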