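presetSettings <- function(preset = c("smoke", "paper")) {
  preset <- match.arg(preset)
  if (preset == "smoke")
    list(scale = 10, trials = 200, maxStore = 100, nRuns = 50,
         tPilot = 8000, step = 20)
  else
    list(scale = 1, trials = 1000, maxStore = 200, nRuns = 500,
         tPilot = 40000, step = 20)
}

#' ON-state lifetime over a grid of dissociation rates
#'
#' Re-derives the expression rates for every combination of own-promoter
#' and target dissociation rates (the only unconstrained parameters), then
#' estimates the mean ON lifetime of each cell by forward flux sampling.
#' The `"smoke"` preset works on the 10-fold copy-number-reduced system
#' with reduced trial counts; `"paper"` runs the full-scale system (long).
#'
#' @param bO Own-promoter dissociation rates scanned (s^-1).
#' @param bT Target dissociation rates scanned (s^-1).
#' @param obs An [observableSet()] supplying the measured copy numbers.
#' @param variant Model variant ("noncoop" or "coop"; the cooperative scan
#'   ties the two sequential dissociation rates `b1 = b2 = bO`).
#' @param fC_given Translation rate used in the derivation chain.
#' @param preset "smoke" or "paper".
#' @param seed Master seed.
#' @param trials,tPilot Optional overrides of the preset's shot count and
#'   pilot length.
#' @return data.frame of class "ScanResult": `bO`, `bT`, `lifetime` (s),
#'   `logSE`, `lowerBoundOnly`, with the scan settings in
#'   `attr(, "manifest")`.
#' @export
lifetimeScan <- function(bO = c(0.1, 1, 10, 100), bT = c(0.1, 1, 10, 100),
                         obs = observableSet(), variant = "noncoop",
                         fC_given = 0.0274, preset = "smoke", seed = 1,
                         trials = NULL, tPilot = NULL) {
  st <- presetSettings(preset)
  if (!is.null(trials)) st$trials <- trials
  if (!is.null(tPilot)) st$tPilot <- tPilot
  grid <- expand.grid(bO = bO, bT = bT)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    binding <- if (variant == "coop")
      c(b1 = grid$bO[i], b2 = grid$bO[i], bT = grid$bT[i])
    else c(bO = grid$bO[i], bT = grid$bT[i])
    ps <- deriveParams(obs, binding = binding, variant = variant,
                       fC_given = fC_given)
    if (st$scale > 1) ps <- scaleParams(ps, st$scale)
    cfg <- placeInterfaces(ps, variant, step = st$step, trials = st$trials,
                           maxStore = st$maxStore,
                           seed = deriveSeed(seed, i), tPilot = st$tPilot)
    res <- ffsRun(ps, variant, cfg)
    data.frame(bO = grid$bO[i], bT = grid$bT[i], lifetime = res@lifetime,
               logSE = res@lifetimeLogSE, lowerBoundOnly = res@lowerBoundOnly)
  })
  out <- do.call(rbind, rows)
  attr(out, "manifest") <- list(preset = preset, seed = seed,
                                settings = st, variant = variant,
                                obs = unclass(obs))
  class(out) <- c("ScanResult", class(out))
  out
}

#' Depletion-panel ensembles
#'
#' Runs transient-depletion ensembles for a stable and an unstable
#' parameterization of the switch (both carrying the reporter-target mRNA)
#' and summarises selector mRNA maintenance during depletion plus recovery
#' fractions as a function of depletion duration.
#'
#' The default stable arm rests at the stable-switch operating point
#' (~900 selector copies) and switches its protein turnover to the printed
#' depletion-phase pair (`bC = 0.0019`, `fC = 0.024`) inside the window,
#' which holds it at the ~100-copy depleted quasi-steady state; the
#' unstable arm uses the printed weak-binding depletion variant and raises
#' degradation `factor`-fold inside the window.
#'
#' @param stable,unstable Arm definitions: a list
#'   `list(params = ParameterSet, overrides = named rates)` giving the
#'   resting parameters and the in-window replacements, or a bare
#'   [ParameterSet] (the window then raises `bC` by `factor`).  Defaults:
#'   the published panel arms, copy-number-scaled under the smoke preset.
#' @param durations Depletion durations (s).
#' @param factor Fold-increase of degradation during depletion.
#' @param preset "smoke" or "paper".
#' @param seed Master seed.
#' @param postWindow Post-depletion observation window (s).
#' @param nRuns Optional override of the preset's ensemble size.
#' @return List with per-switch `summary` data.frames (duration, recovery
#'   fraction + CI, mean mRNA during depletion vs before) and example
#'   trajectories.
#' @export
depletionPanel <- function(stable = NULL, unstable = NULL,
                           durations = c(0, 24, 48) * 3600, factor = 50,
                           preset = "smoke", seed = 1,
                           postWindow = 24 * 3600, nRuns = NULL) {
  st <- presetSettings(preset)
  if (!is.null(nRuns)) st$nRuns <- nRuns
  if (is.null(stable)) {
    p <- paramSet(c(publishedParams("stable4B")@rates, fP = 0.09, bP = 8e-4),
                  NT = 500)
    if (st$scale > 1) p <- scaleParams(p, st$scale)
    stable <- list(params = p, overrides = c(bC = 0.0019, fC = 0.024))
  }
  if (is.null(unstable)) {
    p <- publishedParams("unstable4E")
    if (st$scale > 1) p <- scaleParams(p, st$scale)
    unstable <- list(params = p,
                     overrides = c(bC = factor * rateOf(p, "bC")))
  }
  asArm <- function(x) {
    if (is(x, "ParameterSet"))
      x <- list(params = x, overrides = c(bC = factor * rateOf(x, "bC")))
    x
  }
  armProtocol <- function(arm, d) {
    if (d <= 0) return(NULL)
    ov <- arm$overrides
    protocol(data.frame(tStart = 0, tEnd = d, param = names(ov),
                        value = unname(ov), stringsAsFactors = FALSE))
  }
  onePanel <- function(arm, tag) {
    arm <- asArm(arm)
    ps <- arm$params
    ssOn <- steadyStateObservables(ps, "noncoop")
    runOne <- function(d, sd) runProtocol(ps, "noncoop", armProtocol(arm, d),
                                          tMax = d + postWindow, seed = sd,
                                          sampleDt = 120)
    rows <- lapply(seq_along(durations), function(i) {
      d <- durations[i]
      recovered <- vapply(seq_len(st$nRuns), function(r) {
        tr <- runOne(d, deriveSeed(seed, 1000 * i + r))
        post <- totalSelector(tr)[tr@times >= d]
        any(post >= ssOn$C_total / 2)
      }, TRUE)
      k <- sum(recovered)
      ci <- stats::binom.test(k, st$nRuns)$conf.int
      tr <- runOne(d, deriveSeed(seed, 200 + i))
      inDepl <- tr@times > 0 & tr@times <= max(d, 1)
      data.frame(switch = tag, duration = d,
                 recovery = k / st$nRuns, ciLow = ci[1], ciHigh = ci[2],
                 M_depletion = mean(tr@states[inDepl, "M"]),
                 M_on = ssOn$M_ss)
    })
    list(summary = do.call(rbind, rows),
         trajectory = runOne(max(durations), deriveSeed(seed, 300)))
  }
  list(stable = onePanel(stable, "stable"),
       unstable = onePanel(unstable, "unstable"),
       manifest = list(preset = preset, seed = seed, factor = factor,
                       durations = durations))
}

#' Homeodomain co-factor panel: three in-silico experiments
#'
#' Scores, per co-factor model, the three perturbation experiments used to
#' discriminate the co-factor hypotheses: (1) transient selector-
#' independent induction from the OFF state (`fM0` window) — does
#' expression persist after the window?  (2) deletion of the selector's
#' binding motif in its own promoter (`fO_C = 0`) — is expression lost?
#' (3) transient 50-fold depletion — is expression maintained through and
#' after it?  A run counts as expressing when its mean mRNA over the final
#' observation window exceeds half the deterministic ON value.
#'
#' @param variants HD model variants to score.
#' @param preset "smoke" or "paper".
#' @param nRuns Runs per experiment.
#' @param seed Master seed.
#' @param tInduction,tObserve,tDepletion Phase durations (s).
#' @param scale Copy-number reduction factor.  Unlike the lifetime scans,
#'   this panel defaults to full copy numbers: during 50-fold depletion the
#'   co-factor model holds only a handful of mRNAs and proteins even at
#'   full scale, and any substantial reduction pushes that state into
#'   stochastic extinction, destroying the resilience the experiment
#'   probes.  The run lengths are kept short instead.
#' @return data.frame: variant, experiment, fraction of runs expressing at
#'   the end, and the qualitative call.
#' @export
hdtfPanel <- function(variants = c("hd1a", "hd2a"), preset = "smoke",
                      nRuns = 3, seed = 1, tInduction = 3 * 3600,
                      tObserve = 4 * 3600, tDepletion = 2 * 3600,
                      scale = 1) {
  st <- presetSettings(preset)
  st$scale <- scale
  rows <- list()
  for (v in variants) {
    ps <- publishedParams(v)
    if (st$scale > 1) ps <- scaleParams(ps, st$scale)
    psRun <- setRates(ps, fM0 = 0)  # basal induction only inside windows
    ssOn <- steadyStateObservables(psRun, v)
    mOn <- ssOn$M_ss
    net <- buildNetwork(v, psRun)
    offState <- setNames(numeric(length(net@species)), net@species)
    offState["O"] <- 1
    offState["OTf"] <- psRun@NT
    if ("H" %in% net@species)
      offState["H"] <- if (is.na(psRun@H0)) 0 else psRun@H0
    endMeanM <- function(tr, from) {
      keep <- tr@times >= from
      mean(tr@states[keep, "M"])
    }
    frac <- function(f) mean(vapply(seq_len(nRuns), f, TRUE))
    # (1) transient induction from OFF
    indOn <- frac(function(i) {
      prot <- inductionProtocol(0, tInduction, rateOf(ps, "fM0"))
      tr <- gillespieRun(net, psRun, init = offState,
                         tMax = tInduction + tObserve,
                         seed = deriveSeed(seed, 10 + i),
                         protocol = prot, sampleDt = 120)
      endMeanM(tr, tInduction + tObserve / 2) > mOn / 2
    })
    # (2) motif deletion from ON
    psDel <- motifDeletionParams(psRun)
    netDel <- buildNetwork(v, psDel)
    delOn <- frac(function(i) {
      tr <- gillespieRun(netDel, psDel, init = onStateVector(net, psRun),
                         tMax = tObserve, seed = deriveSeed(seed, 20 + i),
                         sampleDt = 120)
      endMeanM(tr, tObserve / 2) > mOn / 2
    })
    # (3) transient depletion from ON
    depOn <- frac(function(i) {
      prot <- depletionProtocol(psRun, 0, tDepletion)
      tr <- gillespieRun(net, psRun, init = "on",
                         tMax = tDepletion + tObserve,
                         seed = deriveSeed(seed, 30 + i),
                         protocol = prot, sampleDt = 120)
      endMeanM(tr, tDepletion + tObserve / 2) > mOn / 2
    })
    rows[[v]] <- data.frame(
      variant = v,
      experiment = c("induction", "motif_deletion", "depletion"),
      expressing = c(indOn, delOn, depOn),
      reproduces = c(indOn >= 0.65,       # maintenance after induction
                     delOn <= 0.35,       # loss after motif deletion
                     depOn >= 0.65))      # resilience to depletion
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "manifest") <- list(preset = preset, seed = seed, nRuns = nRuns)
  out
}
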