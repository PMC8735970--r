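#' Exact Gillespie simulation of a reaction network
#'
#' Statistically exact stochastic simulation (direct method) of a
#' [ReactionNetwork] under an optional [Protocol].  Steps never cross a
#' protocol boundary: the run is segmented at every override window edge
#' and bleach event, rates are piecewise constant within segments, and
#' bleach events relabel visible protein binomially at their instant.
#' Identical `(network, params, protocol, seed)` give bit-identical
#' trajectories.  An absorbing state simply holds until `tMax`.
#'
#' @param network A [ReactionNetwork].
#' @param params A [ParameterSet].
#' @param init Named initial counts, or `"on"` for the rounded deterministic
#'   ON state.
#' @param tMax End time (s).
#' @param seed Integer seed.
#' @param protocol Optional [Protocol].
#' @param sampleDt Sampling grid spacing (s).
#' @param maxEvents Event budget (error guard).
#' @return A [Trajectory].
#' @examples
#' net <- buildNetwork("noncoop", scaleParams(publishedParams("unstable4B")))
#' tr <- gillespieRun(net, scaleParams(publishedParams("unstable4B")),
#'                    tMax = 200, seed = 1, sampleDt = 10)
#' head(tr@states)
#' @export
gillespieRun <- function(network, params, init = "on", tMax, seed,
                         protocol = NULL, sampleDt = 1, maxEvents = 5e9) {
  stopifnot(tMax > 0)
  set.seed(seed)
  x <- if (identical(init, "on")) onStateVector(network, params)
       else asStateVector(network, init)
  if (any(x < 0)) stop("initial state has negative counts")

  bl <- if (is.null(protocol)) data.frame(t = numeric(0), fraction = numeric(0))
        else protocol@bleaches
  edges <- numeric(0)
  if (!is.null(protocol) && nrow(protocol@overrides))
    edges <- c(protocol@overrides$tStart, protocol@overrides$tEnd)
  edges <- sort(unique(c(edges[edges > 0 & edges < tMax],
                         bl$t[bl$t > 0 & bl$t < tMax], tMax)))
  grid <- seq(sampleDt, tMax, by = sampleDt)
  out <- matrix(0, length(grid), length(network@species))
  filled <- 0L
  tCur <- 0
  nEvents <- 0
  lastExit <- 0L
  xs <- setNames(as.numeric(x), network@species)
  if (nrow(bl) && any(bl$t == 0)) # bleach at t = 0 applies to the initial state
    for (i in which(bl$t == 0)) xs <- bleachState(xs, bl$fraction[i])
  x0row <- round(unname(xs))
  for (segEnd in edges) {
    k <- resolveRates(network, params, t = tCur, protocol = protocol)
    segGrid <- grid[grid > tCur & grid <= segEnd]
    res <- ssa_segment_cpp(as.integer(round(xs)), network@stoich,
                           network@reactants - 1L, k, tCur, segEnd, segGrid,
                           numeric(0), NA_real_, NA_real_, maxEvents)
    if (res$nSamples > 0)
      out[filled + seq_len(res$nSamples), ] <- res$samples[seq_len(res$nSamples), , drop = FALSE]
    filled <- filled + res$nSamples
    xs <- setNames(as.numeric(res$state), network@species)
    nEvents <- nEvents + res$nEvents
    lastExit <- res$exit
    tCur <- segEnd
    if (res$exit == 4L) stop("event budget exhausted at t = ", res$t)
    for (i in which(bl$t == segEnd)) xs <- bleachState(xs, bl$fraction[i])
  }
  states <- rbind(x0row, out[seq_len(filled), , drop = FALSE])
  dimnames(states) <- list(NULL, network@species)
  new("Trajectory", times = c(0, grid[seq_len(filled)]),
      states = states, variant = network@variant, seed = as.numeric(seed),
      eventCount = nEvents,
      protocol = if (is.null(protocol)) protocol() else protocol,
      exit = if (lastExit == 3L) "absorbing" else "tmax")
}

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory (", object@variant, "): ", length(object@times),
      " samples to t = ", max(object@times), " s, ",
      format(object@eventCount, big.mark = ","), " events, seed ",
      object@seed, ", exit '", object@exit, "'\n", sep = "")
})

#' Simulate a perturbation protocol from the ON state
#'
#' Convenience wrapper: builds the variant's network (adding the reporter
#' block when `fP`/`bP` are set and the photobleach ledger when the protocol
#' bleaches), starts from the rounded deterministic ON state and runs
#' [gillespieRun()].
#'
#' @param params A [ParameterSet].
#' @param variant Model variant tag.
#' @param protocol A [Protocol] (may be empty).
#' @param tMax End time (s).
#' @param seed Integer seed.
#' @param sampleDt Sampling grid spacing (s).
#' @return A [Trajectory].
#' @export
runProtocol <- function(params, variant, protocol = NULL, tMax, seed,
                        sampleDt = 60) {
  frap <- !is.null(protocol) && nrow(protocol@bleaches) > 0
  net <- buildNetwork(variant, params, frap = frap)
  gillespieRun(net, params, init = "on", tMax = tMax, seed = seed,
               protocol = protocol, sampleDt = sampleDt)
}

# Low-level: run one constant-rate stretch until an order-parameter stop
# condition fires.  stopW is a named species-weight vector; the run stops
# when sum(w*x) <= stopLow (exit "low") or >= stopHigh (exit "high").
ssaRunStop <- function(network, params, x0, t0, tMax, stopW,
                       stopLow = NA_real_, stopHigh = NA_real_,
                       sampleDt = NULL, maxEvents = 5e9, rates = NULL) {
  w <- setNames(numeric(length(network@species)), network@species)
  w[names(stopW)] <- stopW
  grid <- if (is.null(sampleDt)) numeric(0) else seq(t0 + sampleDt, tMax, by = sampleDt)
  if (is.null(rates)) rates <- resolveRates(network, params)
  res <- ssa_segment_cpp(as.integer(round(asStateVector(network, x0))),
                         network@stoich, network@reactants - 1L, rates,
                         t0, tMax, grid, unname(w), stopLow, stopHigh,
                         maxEvents)
  list(state = setNames(as.numeric(res$state), network@species),
       t = res$t, nEvents = res$nEvents,
       exit = c("tmax", "low", "high", "absorbing", "budget")[res$exit + 1L],
       samples = if (res$nSamples > 0) {
         s <- res$samples[seq_len(res$nSamples), , drop = FALSE]
         colnames(s) <- network@species
         cbind(t = grid[seq_len(res$nSamples)], s)
       })
}

# order-parameter weights defining the OFF state: total selector protein
# plus mRNA; zero iff no selector anywhere and no transcript
offWeights <- function(species) {
  w <- che1Weights(species)
  w["M"] <- 1
  w
}

#' First-passage time to the OFF state
#'
#' Runs the exact simulation from the ON state until the switch is OFF —
#' no selector protein anywhere (free or bound, either ledger) and no
#' selector mRNA — or until `tMax` (censored).  In the non-cooperative
#' model without basal transcription the OFF state is absorbing.
#'
#' @param params A [ParameterSet].
#' @param variant Model variant tag.
#' @param seed Integer seed.
#' @param tMax Censoring time (s).
#' @param init Initial state or `"on"`.
#' @return List: `time` (s, `NA` if censored), `censored`, `events`.
#' @export
firstPassageToOff <- function(params, variant, seed, tMax, init = "on") {
  net <- buildNetwork(variant, params)
  set.seed(seed)
  x0 <- if (identical(init, "on")) onStateVector(net, params)
        else asStateVector(net, init)
  res <- ssaRunStop(net, params, x0, 0, tMax, offWeights(net@species),
                    stopLow = 0)
  if (res$exit %in% c("low", "absorbing") &&
      sum(offWeights(net@species) * res$state) <= 0)
    list(time = res$t, censored = FALSE, events = res$nEvents)
  else
    list(time = NA_real_, censored = TRUE, events = res$nEvents)
}

#' Fraction of runs recovering from transient depletion
#'
#' Simulates `nRuns` depletion episodes (degradation raised `factor`-fold
#' for `duration` seconds, starting from the ON state) and scores the
#' fraction in which total selector protein climbs back above half its ON
#' mean within a post-depletion observation window.  Failures arise from
#' stochastic loss of every selector molecule during depletion, after which
#' the non-cooperative switch cannot restart.
#'
#' @param params A [ParameterSet].
#' @param variant Model variant tag.
#' @param duration Depletion duration (s).
#' @param factor Fold-increase of `bC` during depletion.
#' @param nRuns Ensemble size.
#' @param seed Master seed; per-run seeds are derived deterministically.
#' @param postWindow Post-depletion observation window (s).
#' @param sampleDt Sampling grid (s).
#' @return List: `fraction`, `ci` (95% binomial), `nRuns`, `recovered`
#'   (logical vector).
#' @export
recoveryFraction <- function(params, variant, duration, factor = 50,
                             nRuns = 100, seed = 1, postWindow = 48 * 3600,
                             sampleDt = 120) {
  onMean <- steadyStateObservables(params, variant)$C_total
  prot <- if (duration > 0) depletionProtocol(params, 0, duration, factor)
          else NULL
  recovered <- vapply(seq_len(nRuns), function(i) {
    tr <- runProtocol(params, variant, prot, tMax = duration + postWindow,
                      seed = deriveSeed(seed, i), sampleDt = sampleDt)
    post <- totalSelector(tr)[tr@times >= duration]
    any(post >= onMean / 2)
  }, TRUE)
  k <- sum(recovered)
  ci <- stats::binom.test(k, nRuns)$conf.int
  list(fraction = k / nRuns, ci = as.numeric(ci), nRuns = nRuns,
       recovered = recovered)
}
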