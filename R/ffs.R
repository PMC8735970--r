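#' Characterize the ON basin
#'
#' Long equilibrium run in the ON state; returns the time-averaged mean and
#' variance of total selector protein after discarding a burn-in, plus the
#' mean of the order parameter used by the flux sampler (total selector
#' protein + mRNA).
#'
#' @param params A [ParameterSet].
#' @param variant Model variant tag.
#' @param tBurn Burn-in (s).
#' @param tSample Sampling stretch after burn-in (s).
#' @param seed Integer seed.
#' @param sampleDt Sampling grid (s).
#' @return List: `mean`, `var`, `sd` of total selector protein;
#'   `lambdaMean` of the order parameter; the sampled `trajectory`.
#' @export
characterizeOnBasin <- function(params, variant, tBurn = 2000,
                                tSample = 20000, seed = 1, sampleDt = 5) {
  net <- buildNetwork(variant, params)
  tr <- gillespieRun(net, params, init = "on", tMax = tBurn + tSample,
                     seed = seed, sampleDt = sampleDt)
  keep <- tr@times >= tBurn
  ctot <- totalSelector(tr)[keep]
  lam <- drop(tr@states[keep, , drop = FALSE] %*%
                offWeights(colnames(tr@states)))
  # a metastable ON state can still switch during the pilot; basin moments
  # must come from the pre-switch stretch only
  med <- median(ctot)
  esc <- which(ctot < med / 2)[1]
  if (!is.na(esc)) {
    if (esc < 20) stop("ON state escaped immediately; no basin to characterize")
    ctot <- ctot[seq_len(esc - 1)]
    lam <- lam[seq_len(esc - 1)]
  }
  list(mean = mean(ctot), var = var(ctot), sd = sd(ctot),
       lambdaMean = mean(lam), lambdaSd = sd(lam),
       lambdaMedian = median(lam), lambdaRobustSd = mad(lam),
       switched = !is.na(esc), trajectory = tr,
       lambdaSeries = lam, nKept = length(ctot))
}

#' Place forward-flux-sampling interfaces
#'
#' Chooses the first interface from the ON-basin fluctuations so that an
#' excursion below the basin mean has a 5-10% chance of reaching it: the
#' pilot trajectory is cut into excursions below the mean of the order
#' parameter (total selector protein + mRNA) and the first interface is set
#' at the corresponding quantile of the excursion minima.  Subsequent
#' interfaces descend in fixed steps of `step` until the absorbing OFF
#' boundary (order parameter 0).  If the resulting count falls outside
#' 20-35 the step is adjusted (with a message) to bring it into range.
#'
#' @param params A [ParameterSet].
#' @param variant Model variant tag.
#' @param basin Optional result of [characterizeOnBasin()]; computed from
#'   the pilot settings when missing.
#' @param step Interface spacing in order-parameter units (copies).
#' @param targetFirstProb Target band for the first-crossing probability.
#' @param trials Shots per interface for the eventual run.
#' @param maxStore Stored crossing states per interface.
#' @param seed Integer seed (also used for the pilot).
#' @param tPilot Pilot sampling stretch (s).
#' @return An [FFSConfig].
#' @export
placeInterfaces <- function(params, variant, basin = NULL, step = 20,
                            targetFirstProb = c(0.05, 0.10), trials = 1000,
                            maxStore = 200, seed = 1, tPilot = 20000) {
  if (is.null(basin))
    basin <- characterizeOnBasin(params, variant, tSample = tPilot,
                                 seed = seed)
  lam <- basin$lambdaSeries
  mu <- basin$lambdaMedian
  rsd <- basin$lambdaRobustSd
  below <- lam < mu
  if (!any(below))
    stop("pilot run never left the basin; use a longer pilot")
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  mins <- mapply(function(s, e) min(lam[s:e]),
                 starts[runs$values], ends[runs$values])
  lambda0 <- as.numeric(quantile(mins, mean(targetFirstProb)))
  # the raw minima quantile is noisy on correlated series; anchor it in a
  # corridor around the robust basin moments (deep excursions of a
  # near-Gaussian basin reach median - 1.5..3 sd with roughly the target
  # probability), with a floor well above the committed region
  lambda0 <- min(max(lambda0, mu - 3 * rsd), mu - 1.5 * rsd)
  lambda0 <- max(lambda0, mu / 3)
  lambda0 <- min(floor(lambda0), floor(mu) - 1)
  lambda0 <- max(lambda0, 1)
  if (step >= mu) stop("interface step must be smaller than the basin mean")
  ifc <- unique(c(seq(lambda0, 0, by = -step), 0))
  n <- length(ifc)
  if (n < 20 || n > 35) {
    step2 <- max(1, ceiling(lambda0 / 30))
    if (lambda0 / step2 + 1 < 20) step2 <- max(1, floor(lambda0 / 20))
    message("adjusting interface step from ", step, " to ", step2,
            " to keep the interface count in [20, 35]")
    step <- step2
    ifc <- unique(c(seq(lambda0, 0, by = -step), 0))
  }
  new("FFSConfig", lambdaOn = mu, lambdaA = lambda0 + step,
      interfaces = ifc, trials = trials, maxStore = maxStore,
      seed = as.numeric(seed))
}

setMethod("show", "FFSConfig", function(object) {
  cat("FFSConfig: ", length(object@interfaces), " interfaces from ",
      object@interfaces[1], " down to 0 (basin mean ",
      signif(object@lambdaOn, 4), ", return boundary ", object@lambdaA,
      "), ", object@trials, " trials/interface\n", sep = "")
})

#' Direct forward flux sampling of ON-to-OFF switching
#'
#' Estimates the spontaneous switching rate as the flux of trajectories
#' through the first interface times the product of conditional
#' interface-crossing probabilities (direct FFS, no pruning).  Stage 0
#' measures the flux by running in the basin and counting first-interface
#' crossings (one per basin excursion); each later stage fires `trials`
#' shots from stored crossing configurations, each shot running until it
#' reaches the next interface or returns to the basin boundary.  The mean
#' ON lifetime is `1/(flux0 * prod(p))`, with the delta-method standard
#' error on the log scale from per-stage binomial variances and the Poisson
#' crossing count.
#'
#' @param params A [ParameterSet].
#' @param variant Model variant tag.
#' @param config An [FFSConfig].
#' @param pathDt When positive, shots record their states every `pathDt`
#'   seconds so complete ON-to-OFF transition paths can be harvested.
#' @param maxCross0 First-interface crossings collected in stage 0.
#' @param tMax0 Stage-0 time budget (s).
#' @return An [FFSResult].
#' @export
ffsRun <- function(params, variant, config, pathDt = 0, maxCross0 = NULL,
                   tMax0 = 2e6) {
  net <- buildNetwork(variant, params)
  w <- offWeights(net@species)
  ifc <- config@interfaces
  n <- length(ifc)
  if (is.null(maxCross0)) maxCross0 <- max(config@maxStore, 100)
  rates <- resolveRates(net, params)
  set.seed(config@seed)

  # --- stage 0: initial flux through the first interface ------------------
  x <- onStateVector(net, params)
  t <- 0
  stores <- vector("list", n)       # states stored at each interface
  parents <- vector("list", n)      # index of the parent one interface up
  segs <- vector("list", n)         # recorded path segments per stored state
  cross0 <- list()
  nCross <- 0L
  while (nCross < maxCross0 && t < tMax0) {
    res <- ssaRunStop(net, params, x, t, tMax0, w, stopLow = ifc[1],
                      rates = rates)
    t <- res$t
    if (res$exit != "low") break
    nCross <- nCross + 1L
    if (length(cross0) < config@maxStore)
      cross0[[length(cross0) + 1L]] <- res$state
    # climb back into the basin before counting another crossing
    res <- ssaRunStop(net, params, res$state, t, tMax0, w,
                      stopLow = 0, stopHigh = config@lambdaA, rates = rates)
    t <- res$t
    if (res$exit == "high") {
      x <- res$state
    } else if (res$exit %in% c("low", "absorbing")) {
      # a full spontaneous switch happened during the return leg;
      # restart in the ON basin and keep counting
      x <- onStateVector(net, params)
    } else break
  }
  if (nCross == 0L)
    stop("no first-interface crossing in the stage-0 budget; ",
         "lengthen tMax0 or move the first interface closer to the basin")
  flux0 <- nCross / t
  stores[[1]] <- cross0
  parents[[1]] <- rep(NA_integer_, length(cross0))
  segs[[1]] <- vector("list", length(cross0))

  # --- stages 1..n-1: conditional crossing probabilities ------------------
  p <- pErr <- rep(NA_real_, n - 1)
  lower <- FALSE
  for (i in seq_len(n - 1)) {
    from <- stores[[i]]
    if (!length(from)) { lower <- TRUE; break }
    succ <- list(); par <- integer(0); seg <- list()
    nSucc <- 0L; nTry <- 0L
    # shots are short compared to the basin relaxation time; the horizon
    # mainly bounds the recording grid when paths are collected
    shotTmax <- if (pathDt > 0) 2e4 * pathDt else 5e7
    for (k in seq_len(config@trials)) {
      j <- sample.int(length(from), 1)      # with replacement
      res <- ssaRunStop(net, params, from[[j]], 0, shotTmax, w,
                        stopLow = ifc[i + 1], stopHigh = config@lambdaA,
                        sampleDt = if (pathDt > 0) pathDt else NULL,
                        rates = rates)
      nTry <- nTry + 1L
      hitLow <- res$exit %in% c("low", "absorbing") &&
        sum(w * res$state) <= ifc[i + 1]
      if (hitLow) {
        nSucc <- nSucc + 1L
        if (length(succ) < config@maxStore) {
          succ[[length(succ) + 1L]] <- res$state
          par <- c(par, j)
          seg[[length(succ)]] <- if (pathDt > 0)
            rbind(res$samples,
                  c(res$t, res$state)) else NULL
        }
      }
    }
    p[i] <- nSucc / nTry
    pErr[i] <- sqrt(max(p[i] * (1 - p[i]), 1 / nTry^2) / nTry)
    stores[[i + 1]] <- succ
    parents[[i + 1]] <- par
    segs[[i + 1]] <- seg
    if (nSucc == 0L) { lower <- TRUE; break }
  }

  pUse <- p
  if (lower) pUse[is.na(pUse) | pUse == 0] <- 1 / config@trials
  rate <- flux0 * prod(pUse, na.rm = TRUE)
  lifetime <- 1 / rate
  varLog <- 1 / nCross +
    sum(((1 - p) / pmax(p, 1 / config@trials)) / config@trials, na.rm = TRUE)

  paths <- list()
  if (pathDt > 0 && !lower && length(stores[[n]])) {
    for (idx in seq_along(stores[[n]])) {
      chain <- list()
      i <- n; j <- idx
      ok <- TRUE
      while (i >= 2) {
        sg <- segs[[i]][[j]]
        if (is.null(sg)) { ok <- FALSE; break }
        chain[[length(chain) + 1L]] <- sg
        j <- parents[[i]][j]
        i <- i - 1
      }
      if (ok && length(chain)) {
        chain <- rev(chain)
        off <- 0
        for (ci in seq_along(chain)) {
          chain[[ci]][, 1] <- chain[[ci]][, 1] + off
          off <- max(chain[[ci]][, 1])
        }
        paths[[length(paths) + 1L]] <- do.call(rbind, chain)
      }
    }
  }

  new("FFSResult", config = config, flux0 = flux0, nCross0 = as.numeric(nCross),
      p = p, pErr = pErr, lifetime = lifetime, lifetimeLogSE = sqrt(varLog),
      lowerBoundOnly = lower, paths = paths, species = net@species)
}

setMethod("show", "FFSResult", function(object) {
  cat("FFSResult: flux0 = ", signif(object@flux0, 3), "/s over ",
      object@nCross0, " crossings; ", sum(!is.na(object@p)),
      " staged probabilities\n", sep = "")
  cat(if (object@lowerBoundOnly) "lifetime (lower bound) >= " else "lifetime = ",
      signif(object@lifetime, 4), " s (log-SE ",
      signif(object@lifetimeLogSE, 2), "), ",
      length(object@paths), " complete transition path(s)\n", sep = "")
})

#' Mean transition-path profiles versus selector level
#'
#' Bins the states recorded along complete ON-to-OFF transition paths by
#' total selector protein and returns, per bin, the mean occupancy of the
#' selector's own promoter, the mean fraction of occupied target promoters
#' and the mean mRNA count.  Harvested paths are branches of the FFS shot
#' tree traced back from OFF, so each carries equal weight.
#'
#' @param result An [FFSResult] run with `pathDt > 0`.
#' @param breaks Bin edges on total selector protein, or a bin count.
#' @return data.frame: `C_mid`, `theta_own`, `target_occ`, `M`, `nObs`.
#' @export
averageTransitionPath <- function(result, breaks = 10) {
  if (!length(result@paths))
    stop("result contains no complete transition path; rerun with pathDt > 0")
  sp <- result@species
  all <- do.call(rbind, result@paths)
  states <- all[, -1, drop = FALSE]
  colnames(states) <- sp
  ctot <- drop(states %*% che1Weights(sp))
  own <- intersect(c("OC", "OC2", "OH", "OHC", "OCd"), sp)
  ownBound <- rowSums(states[, intersect(c("OC", "OC2", "OHC", "OCd"), sp),
                             drop = FALSE] > 0)
  thetaOwn <- pmin(ownBound, 1)
  NT <- states[, "OTf"] + states[, "OTC"]
  tOcc <- states[, "OTC"] / pmax(NT, 1)
  if (length(breaks) == 1)
    breaks <- seq(0, max(ctot) + 1e-9, length.out = breaks + 1)
  bin <- cut(ctot, breaks, include.lowest = TRUE)
  agg <- function(v) tapply(v, bin, mean)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  data.frame(C_mid = mids,
             theta_own = as.numeric(agg(thetaOwn)),
             target_occ = as.numeric(agg(tOcc)),
             M = as.numeric(agg(states[, "M"])),
             nObs = as.numeric(table(bin)))
}
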