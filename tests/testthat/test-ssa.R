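test_that("birth-death fixture reproduces the Poisson stationary law", {
  net <- birthDeathNetwork()
  p <- paramSet(f = 2, b = 0.1, NT = 1)
  tr <- gillespieRun(net, p, init = c(X = 0), tMax = 20000, seed = 42,
                     sampleDt = 1)
  x <- tr@states[tr@times > 200, "X"]
  se <- batchSE(x)
  expect_lt(abs(mean(x) - 20), 3 * se)
  # chi-square goodness of fit against Poisson(20), thinned for independence
  xt <- x[seq(1, length(x), by = 25)]
  ks <- 8:32
  obs <- table(factor(pmin(pmax(xt, 8), 32), levels = ks))
  pr <- dpois(ks, 20)
  pr[1] <- ppois(8, 20)
  pr[length(ks)] <- 1 - ppois(31, 20)
  gof <- suppressWarnings(chisq.test(obs, p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("an absorbing state holds until the end of the run", {
  p <- publishedParams("unstable4B")
  net <- buildNetwork("noncoop", p)
  off <- c(O = 1, OC = 0, OTf = 500, OTC = 0, M = 0, C = 0)
  tr <- gillespieRun(net, p, init = off, tMax = 500, seed = 1, sampleDt = 10)
  expect_true(all(tr@states[, "M"] == 0))
  expect_true(all(tr@states[, "C"] == 0))
  expect_equal(tr@exit, "absorbing")
  expect_equal(tr@eventCount, 0)
})

test_that("identical configuration and seed give identical trajectories", {
  ps <- tinyUnstable()
  net <- buildNetwork("noncoop", ps)
  a <- gillespieRun(net, ps, tMax = 500, seed = 11, sampleDt = 5)
  b <- gillespieRun(net, ps, tMax = 500, seed = 11, sampleDt = 5)
  expect_identical(a@states, b@states)
  expect_identical(a@eventCount, b@eventCount)
  # an empty protocol is the same stochastic process, same stream
  c <- gillespieRun(net, ps, tMax = 500, seed = 11, protocol = protocol(),
                    sampleDt = 5)
  expect_identical(a@states, c@states)
  d <- gillespieRun(net, ps, tMax = 500, seed = 12, sampleDt = 5)
  expect_false(identical(a@states, d@states))
})

test_that("clamped-ligand site binding reaches the analytic occupancy", {
  # kon = fO * C with C clamped at 80; koff = bT; NT = 50 sites
  fO <- 0.3; C0 <- 80; bT <- 100; NT <- 50
  net <- clampedBindingNetwork()
  p <- paramSet(kon = fO * C0, koff = bT, NT = NT)
  tr <- gillespieRun(net, p, init = c(OTf = NT, OTC = 0), tMax = 400,
                     seed = 3, sampleDt = 0.05)
  occ <- tr@states[tr@times > 5, "OTC"] / NT
  thExp <- fO * C0 / (fO * C0 + bT)
  expect_lt(abs(mean(occ) - thExp), 3 * batchSE(occ))
})

test_that("the weakly stable switch fluctuates around the measured mRNA count", {
  p <- publishedParams("unstable4B")
  net <- buildNetwork("noncoop", p)
  tr <- gillespieRun(net, p, init = "on", tMax = 10000, seed = 7, sampleDt = 5)
  m <- tr@states[, "M"]
  expect_lt(abs(mean(m) - 7), 3 * max(batchSE(m, 10), 0.5))
})

test_that("first passage to OFF honours its contract at the edges", {
  ps <- tinyUnstable()
  net <- buildNetwork("noncoop", ps)
  off <- setNames(numeric(length(net@species)), net@species)
  off["O"] <- 1; off["OTf"] <- ps@NT
  r0 <- firstPassageToOff(ps, "noncoop", seed = 1, tMax = 100, init = off)
  expect_equal(r0$time, 0)
  expect_false(r0$censored)
  # a strongly stable switch does not switch in a short window
  stable <- publishedParams("stable4B")
  rc <- firstPassageToOff(stable, "noncoop", seed = 1, tMax = 30)
  expect_true(rc$censored)
})

test_that("two independent first-passage ensembles agree", {
  ps <- tinyUnstable()
  fpt <- function(seeds) vapply(seeds, function(s)
    firstPassageToOff(ps, "noncoop", seed = s, tMax = 2e6)$time, 0)
  a <- fpt(1:12)
  b <- fpt(101:112)
  expect_true(all(!is.na(c(a, b))))
  seA <- sd(a) / sqrt(length(a))
  seB <- sd(b) / sqrt(length(b))
  expect_lt(abs(mean(a) - mean(b)), 2 * sqrt(seA^2 + seB^2) + 1e-9)
})

test_that("recovery fraction is 1 without depletion and falls with duration", {
  ps <- tinyUnstable()
  r0 <- recoveryFraction(ps, "noncoop", duration = 0, nRuns = 5, seed = 2,
                         postWindow = 600, sampleDt = 60)
  expect_equal(r0$fraction, 1)
  # long, deep depletion kills every selector molecule and recovery fails
  rLong <- recoveryFraction(ps, "noncoop", duration = 36 * 3600, factor = 50,
                            nRuns = 5, seed = 3, postWindow = 3600,
                            sampleDt = 300)
  expect_equal(rLong$fraction, 0)
})

test_that("bleach events move protein to the dark ledger and conserve totals", {
  ps <- publishedParams("stable4B")
  net <- buildNetwork("noncoop", ps, frap = TRUE)
  prot <- bleachProtocol(t = 100, fraction = 0.8)
  tr <- gillespieRun(net, ps, init = "on", tMax = 200, seed = 5,
                     protocol = prot, sampleDt = 10)
  tot <- totalSelector(tr)
  vis <- totalSelector(tr, visibleOnly = TRUE)
  iBefore <- max(which(tr@times < 100))
  iAfter <- iBefore + 2
  expect_equal(vis[iBefore], tot[iBefore])      # nothing dark before
  expect_lt(vis[iAfter], 0.4 * tot[iAfter])     # ~80% went dark
  expect_lt(abs(tot[iAfter] - tot[iBefore]), 0.2 * tot[iBefore])
})
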