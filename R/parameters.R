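#' Construct a ParameterSet
#'
#' @param ... Named rate constants in s^-1 (see [ParameterSet-class] for the
#'   recognised symbols), or a single named numeric vector / list.
#' @param NT Number of identical target promoters.
#' @param H0 Clamped free HD-TF copy number for constitutive co-factor
#'   variants; `NA` when unused.
#' @return A validated [ParameterSet].
#' @examples
#' p <- paramSet(fO = 0.03, bO = 100, bT = 100, fM = 0.0302,
#'               bM = 0.00083, fC = 0.0274, bC = 0.00024, NT = 500)
#' rateOf(p, "fM")
#' @export
paramSet <- function(..., NT = 500, H0 = NA_real_) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) &&
      (is.numeric(dots[[1]]) || is.list(dots[[1]])))
    dots <- as.list(dots[[1]])
  rates <- unlist(dots)
  new("ParameterSet", rates = rates, NT = as.numeric(NT), H0 = as.numeric(H0))
}

#' @describeIn paramSet Look up one rate (error if absent and no default).
#' @param params A [ParameterSet].
#' @param name Rate symbol.
#' @param default Value returned when the rate is absent.
#' @export
rateOf <- function(params, name, default = NULL) {
  r <- params@rates
  if (name %in% names(r)) return(unname(r[[name]]))
  if (!is.null(default)) return(default)
  stop("parameter set is missing required rate '", name, "'", call. = FALSE)
}

#' @describeIn paramSet Return a modified copy with rates replaced or added.
#' @export
setRates <- function(params, ...) {
  upd <- unlist(list(...))
  r <- params@rates
  r[names(upd)] <- upd
  initialize(params, rates = r)
}

setMethod("show", "ParameterSet", function(object) {
  cat("ParameterSet with", length(object@rates), "rates, NT =", object@NT)
  if (!is.na(object@H0)) cat(", H0 =", object@H0)
  cat("\n")
  print(signif(object@rates, 4))
})

#' Parameter sets of the published switch variants
#'
#' Returns the printed parameter tables for the bistable-switch figures:
#' the weakly stable ("unstable") and highly stable non-cooperative switches,
#' the two depletion-panel variants that carry a reporter-target mRNA, and
#' the four homeodomain co-factor (HD-TF) models.  All rates in s^-1.
#'
#' `bM` is stored at the unrounded 1/1200 s^-1 (mean mRNA lifetime 20 min);
#' the printed 0.00083 is its two-significant-figure form.  Use
#' `roundedBM = TRUE` for the rounded table value.
#'
#' @param which One of "unstable4B", "stable4B", "stable4E", "unstable4E",
#'   "hd1a", "hd1b", "hd2a", "hd2b".
#' @param NT Target promoter count (500 or 1000 in the study).
#' @param roundedBM Use the printed two-significant-figure mRNA decay rate.
#' @return A [ParameterSet].
#' @export
publishedParams <- function(which = c("unstable4B", "stable4B", "stable4E",
                                  "unstable4E", "hd1a", "hd1b", "hd2a", "hd2b"),
                        NT = 500, roundedBM = FALSE) {
  which <- match.arg(which)
  bM <- if (roundedBM) 0.00083 else 1 / 1200
  base <- c(fO = 0.03, bO = 100, bT = 100, fM = 0.0302, bM = bM,
            fC = 0.0274, bC = 0.00024)
  p <- switch(which,
    unstable4B = base,
    stable4B = replace(base, c("bO", "fM", "fC", "bC"),
                       c(0.1, 0.0059, 0.0261, 0.00023)),
    stable4E = c(replace(base, c("bO", "fM", "fC", "bC"),
                         c(0.1, 0.0059, 0.024, 0.0019)),
                 fP = 0.09, bP = 0.0008),
    unstable4E = c(replace(base, c("bO", "bT", "fC", "bC"),
                           c(10, 10, 0.026, 0.00076)),
                   fP = 0.016, bP = 0.0004),
    { # HD-TF models share a common block
      hd <- c(fO = 0.03, fO_C = 0.03, fO_H = 0.03, bO = 100, bT = 100,
              fM = 0.0085, bM = bM, fC = 0.0198, bC = 0.00032, fM0 = 0.005)
      if (which %in% c("hd1a", "hd1b")) hd <- c(hd, bO_s = 0.1)
      if (which %in% c("hd2a", "hd2b")) {
        hd[["fM"]] <- 0.01
        hd <- c(hd, fM_H = 0.015)
      }
      if (which %in% c("hd1b", "hd2b")) hd <- c(hd, fH = 0.0001, bH = 0.000015)
      hd
    })
  ps <- paramSet(p, NT = NT)
  if (which %in% c("hd1a", "hd2a")) ps@H0 <- hdConstitutiveH0(which, NT = NT)
  ps
}

#' Default clamped HD-TF copy number for constitutive variants
#'
#' The constitutive models hold free HD-TF at a fixed count `H0`.  The study
#' leaves this number open; the default matches the selector-controlled
#' variant of the same model: `H0 = round(fH * C_ss / bH)` evaluated at the
#' deterministic ON fixed point of that variant, so promoter-site occupancy
#' by HD-TF agrees between the paired variants.
#'
#' @param which "hd1a" or "hd2a".
#' @param NT Target promoter count.
#' @return Integer-valued copy number.
#' @export
hdConstitutiveH0 <- function(which = c("hd1a", "hd2a"), NT = 500) {
  which <- match.arg(which)
  bvar <- sub("a$", "b", which)
  pb <- publishedParams(bvar, NT = NT)
  fp <- findFixedPoints(pb, bvar)
  on <- fp[[which.max(vapply(fp, function(f) f$state[["C"]], 0))]]
  round(rateOf(pb, "fH") * on$state[["C"]] / rateOf(pb, "bH"))
}

#' System-size scaling of a parameter set
#'
#' Rescales every copy number by `1/factor` while preserving occupancies and
#' deterministic structure: bimolecular association rates (`fO`, `fO_C`,
#' `fO_H`) are multiplied by `factor` (volume shrinks), per-promoter
#' production rates (`fM`, `fM_H`, `fP`) and the zeroth-order basal rate
#' `fM0` are divided by `factor` (promoter copy number cannot scale), `NT`
#' and `H0` are divided by `factor`, and all first-order rates are left
#' unchanged.  Used for the reduced-copy-number "smoke" fixtures whose
#' switching events are frequent enough for brute-force simulation.
#'
#' @param params A [ParameterSet].
#' @param factor Copy-number reduction factor (default 10).
#' @return A [ParameterSet] for the scaled-down system.
#' @export
scaleParams <- function(params, factor = 10) {
  r <- params@rates
  up <- intersect(c("fO", "fO_C", "fO_H"), names(r))
  dn <- intersect(c("fM", "fM_H", "fP", "fM0"), names(r))
  r[up] <- r[up] * factor
  r[dn] <- r[dn] / factor
  initialize(params, rates = r, NT = max(1, round(params@NT / factor)),
             H0 = if (is.na(params@H0)) NA_real_ else round(params@H0 / factor))
}

#' Measured observables from which simulation rates are derived
#'
#' @param C_total Mean selector protein copies per cell.
#' @param M_ss Mean selector mRNA copies per cell.
#' @param mRNA_mean_lifetime Mean mRNA lifetime in seconds.
#' @param protein_half_life_target Protein FRAP recovery half-time target (s).
#' @param sigma Reaction cross-section of a promoter binding site (um).
#' @param D Nuclear diffusion coefficient (um^2/s).
#' @param V_C Nuclear volume (um^3).
#' @param NT Target promoter count.
#' @return A named list of class "ObservableSet".
#' @export
observableSet <- function(C_total = 900, M_ss = 7, mRNA_mean_lifetime = 1200,
                          protein_half_life_target = 83 * 60, sigma = 0.01,
                          D = 1, V_C = 4, NT = 500) {
  obs <- list(C_total = C_total, M_ss = M_ss,
              mRNA_mean_lifetime = mRNA_mean_lifetime,
              protein_half_life_target = protein_half_life_target,
              sigma = sigma, D = D, V_C = V_C, NT = NT)
  if (any(unlist(obs) <= 0)) stop("all observables must be positive")
  class(obs) <- "ObservableSet"
  obs
}

#' Diffusion-limited promoter association rate
#'
#' `4 * pi * sigma * D / V_C`: the Smoluchowski encounter rate of a
#' transcription factor with a promoter site of cross-section `sigma`,
#' divided by the nuclear volume so it applies to molecule counts.
#'
#' @param sigma Reaction cross-section (um).
#' @param D Diffusion coefficient (um^2/s).
#' @param V_C Nuclear volume (um^3).
#' @return Association rate in s^-1 per free-molecule/free-site pair.
#' @examples
#' diffusionLimitedRate(0.01, 1, 4) # ~0.031, quoted as 0.03 at 1 sig. fig.
#' @export
diffusionLimitedRate <- function(sigma, D, V_C) {
  if (any(c(sigma, D, V_C) <= 0)) stop("sigma, D and V_C must be positive")
  4 * pi * sigma * D / V_C
}

#' First-order rate from a mean lifetime
#'
#' Mean-lifetime convention: `rate = 1/tau` (not `ln(2)/t_half`).
#'
#' @param tau Mean lifetime in seconds.
#' @return Decay rate in s^-1.
#' @examples
#' rateFromMeanLifetime(1200) # 20-min mRNA lifetime -> 0.00083 s^-1
#' @export
rateFromMeanLifetime <- function(tau) {
  if (any(tau <= 0)) stop("mean lifetime must be positive")
  1 / tau
}

# Promoter occupancy functions at clamped free-selector count x (and free
# HD-TF count h for co-factor variants).  Returns the stationary probability
# of each promoter configuration plus the mean selector copies sequestered
# on the selector's own promoter ("stoich") and the productive occupancy
# driving transcription.
promoterOccupancy <- function(x, params, variant, h = 0) {
  fO <- rateOf(params, "fO")
  if (variant == "noncoop") {
    fOC <- rateOf(params, "fO_C", fO)
    th <- fOC * x / (fOC * x + rateOf(params, "bO"))
    list(theta = c(OC = th), stoich = th, productive = th, thetaO = th)
  } else if (variant == "coop") {
    b1 <- rateOf(params, "b1", rateOf(params, "bO", NULL))
    b2 <- rateOf(params, "b2", b1)
    k1 <- fO * x / b1
    k2 <- fO * x / b2
    Z <- 1 + k1 + k1 * k2
    th1 <- k1 / Z
    th2 <- k1 * k2 / Z
    list(theta = c(OC = th1, OC2 = th2), stoich = th1 + 2 * th2,
         productive = th2, thetaO = th1 + th2)
  } else { # hd*: 4-state promoter {O, OC, OH, OHC}
    fOC <- rateOf(params, "fO_C")
    fOH <- rateOf(params, "fO_H")
    bO <- rateOf(params, "bO")
    model1 <- variant %in% c("hd1a", "hd1b")
    bOs <- if (model1) rateOf(params, "bO_s") else NA_real_
    # the promoter cycle {O, OC, OH, OHC} satisfies detailed balance
    # (forward and backward rate products around the ring agree), so the
    # stationary weights are products of binding constants; OHC is only
    # reachable in model 1
    wOC <- fOC * x / bO
    wOH <- fOH * h / bO
    wOHC <- if (model1) wOC * (fOH * h / bOs) else 0
    pr <- c(O = 1, OC = wOC, OH = wOH, OHC = wOHC)
    pr <- pr / sum(pr)
    productive <- if (model1) pr[["OC"]] + pr[["OHC"]] else pr[["OC"]]
    list(theta = pr[-1], stoich = pr[["OC"]] + pr[["OHC"]],
         productive = productive, thetaO = pr[["OC"]] + pr[["OHC"]])
  }
}

#' Solve the selector-conservation binding equilibrium
#'
#' With production and decay switched off, the total selector pool
#' `C_total` distributes over free molecules, the selector's own promoter
#' and `NT` identical target promoters.  Solves
#' `x + NT * fO*x/(fO*x + bT) + (own-promoter stoichiometry) = C_total`
#' for the free count `x`; the left side is strictly increasing in `x`, so
#' the root is unique.
#'
#' @param C_total Total selector protein copies.
#' @param params A [ParameterSet] carrying `fO`, `bT` and the own-promoter
#'   dissociation rates of the variant.
#' @param variant Model variant tag.
#' @param tol Relative root tolerance.
#' @return A list of class "EquilibriumSolution": `C_free`, `theta_O`
#'   (own-promoter occupancy), `nT_bound_mean`, `residual`.
#' @examples
#' p <- publishedParams("unstable4B")
#' eq <- solveBindingEquilibrium(900, p, "noncoop")
#' eq$C_free    # ~803
#' eq$theta_O   # ~0.194
#' @export
solveBindingEquilibrium <- function(C_total, params, variant = "noncoop",
                                    tol = 1e-12) {
  fO <- rateOf(params, "fO")
  bT <- rateOf(params, "bT")
  NT <- params@NT
  g <- function(x) {
    occ <- promoterOccupancy(x, params, variant)
    x + NT * fO * x / (fO * x + bT) + occ$stoich - C_total
  }
  if (g(0) > 0 || g(C_total) < 0)
    stop("no binding-equilibrium root in [0, C_total]")
  root <- uniroot(g, c(0, C_total), tol = tol * max(C_total, 1))$root
  occ <- promoterOccupancy(root, params, variant)
  structure(list(C_free = root, theta_O = unname(occ$thetaO),
                 theta_productive = unname(occ$productive),
                 nT_bound_mean = NT * fO * root / (fO * root + bT),
                 residual = g(root)),
            class = "EquilibriumSolution")
}

#' Derive expression rates from measured copy numbers
#'
#' Given the measured mean mRNA and protein copy numbers and the binding
#' equilibrium, the transcription rate follows from mRNA balance,
#' `fM = bM * M_ss / theta_productive`, and the free-protein decay rate from
#' protein balance, `bC = fC * M_ss / C_free`.  `bM` is taken at the
#' unrounded inverse mean lifetime.
#'
#' @param obs An [observableSet()].
#' @param eq An EquilibriumSolution from [solveBindingEquilibrium()] computed
#'   at the same parameters.
#' @param fC_given Translation rate in s^-1 (measured/fitted).
#' @return List with full-precision `fM`, `bC`, `bM`, and two-significant-
#'   figure presentation values `fM_2sf`, `bC_2sf` for table comparison.
#' @examples
#' obs <- observableSet()
#' eq <- solveBindingEquilibrium(900, publishedParams("unstable4B"), "noncoop")
#' deriveExpressionRates(obs, eq, fC_given = 0.0274)$fM_2sf # 0.030
#' @export
deriveExpressionRates <- function(obs, eq, fC_given) {
  if (eq$theta_productive <= 0)
    stop("productive promoter occupancy is zero; no expression possible")
  bM <- rateFromMeanLifetime(obs$mRNA_mean_lifetime)
  fM <- bM * obs$M_ss / eq$theta_productive
  bC <- fC_given * obs$M_ss / eq$C_free
  list(fM = fM, bC = bC, bM = bM,
       fM_2sf = signif(fM, 2), bC_2sf = signif(bC, 2))
}

#' Full parameter derivation from observables
#'
#' Convenience wrapper running the whole derivation chain: diffusion-limited
#' association rate, mRNA decay from the mean lifetime, binding equilibrium
#' at the measured total protein, then transcription and protein-decay rates.
#'
#' @param obs An [observableSet()].
#' @param binding Named vector of dissociation rates (e.g. `c(bO = 100,
#'   bT = 100)`).
#' @param variant Model variant.
#' @param fC_given Translation rate in s^-1.
#' @return A [ParameterSet] with a `derivation` attribute describing each step.
#' @export
deriveParams <- function(obs, binding = c(bO = 100, bT = 100),
                         variant = "noncoop", fC_given = 0.0274) {
  fO <- diffusionLimitedRate(obs$sigma, obs$D, obs$V_C)
  bM <- rateFromMeanLifetime(obs$mRNA_mean_lifetime)
  pbind <- paramSet(c(fO = fO, binding), NT = obs$NT)
  eq <- solveBindingEquilibrium(obs$C_total, pbind, variant)
  ex <- deriveExpressionRates(obs, eq, fC_given)
  ps <- paramSet(c(fO = fO, binding, fM = ex$fM, bM = bM,
                   fC = fC_given, bC = ex$bC), NT = obs$NT)
  attr(ps, "derivation") <- list(
    fO = sprintf("4*pi*sigma*D/V_C = %.4g s^-1", fO),
    bM = sprintf("1/mean mRNA lifetime = %.4g s^-1", bM),
    equilibrium = eq,
    fM = sprintf("bM*M_ss/theta_productive = %.4g s^-1", ex$fM),
    bC = sprintf("fC*M_ss/C_free = %.4g s^-1", ex$bC))
  ps
}

#' Calibrate protein turnover to a photobleaching recovery half-time
#'
#' Finds the `(fC, bC)` pair that (i) keeps the steady state at the measured
#' copy numbers, `fC * M_ss = bC * C_free`, and (ii) gives a deterministic
#' fluorescence-recovery half-time equal to `target_half_life`.  Recovery is
#' computed on the two-ledger (visible/bleached) mean-field model: after the
#' bleach only visible protein is translated while both ledgers bind,
#' unbind and decay identically; the half-time is the time at which the
#' visible total climbs halfway from its post-bleach value to its plateau.
#' The search is one-dimensional in `bC`.
#'
#' @param params A [ParameterSet] with the binding rates fixed.
#' @param obs An [observableSet()]; supplies `C_total`, `M_ss` and the
#'   bleach depth context.
#' @param target_half_life Target recovery half-time (s).
#' @param variant Model variant (photobleach ledger supported for
#'   "noncoop").
#' @param bleach_fraction Fraction of visible protein turned dark at t = 0.
#' @return List `fC`, `bC`, `achieved_half_life`.
#' @export
calibrateProteinRatesToFrap <- function(params, obs, target_half_life,
                                        variant = "noncoop",
                                        bleach_fraction = 0.8) {
  if (target_half_life <= 0) stop("target half-life must be positive")
  eq <- solveBindingEquilibrium(obs$C_total, params, variant)
  halfTime <- function(bC) {
    fC <- bC * eq$C_free / obs$M_ss
    frapHalfTimeDeterministic(params, obs, fC, bC, variant, bleach_fraction)
  }
  # recovery half-time decreases monotonically in bC; bracket then root-solve
  lo <- 1e-7; hi <- 1
  if (halfTime(lo) < target_half_life)
    stop("target half-life longer than attainable: increase the search floor")
  if (halfTime(hi) > target_half_life)
    stop("target half-life shorter than the binding-limited bound")
  bC <- uniroot(function(b) halfTime(b) - target_half_life, c(lo, hi),
                tol = 1e-10)$root
  fC <- bC * eq$C_free / obs$M_ss
  list(fC = fC, bC = bC, achieved_half_life = halfTime(bC))
}

# Deterministic FRAP recovery half-time on the visible/bleached two-ledger
# mean-field model of the given variant.
frapHalfTimeDeterministic <- function(params, obs, fC, bC, variant,
                                      bleach_fraction) {
  ps <- setRates(params, fC = fC, bC = bC,
                 bM = rateFromMeanLifetime(obs$mRNA_mean_lifetime))
  if (!("fM" %in% names(ps@rates))) {
    eq <- solveBindingEquilibrium(obs$C_total, ps, variant)
    ps <- setRates(ps, fM = rateFromMeanLifetime(obs$mRNA_mean_lifetime) *
                     obs$M_ss / eq$theta_productive)
  }
  net <- buildNetwork(variant, ps, frap = TRUE)
  ss <- steadyStateObservables(ps, variant)
  x0 <- onStateVector(net, ps, continuous = TRUE)
  x0 <- bleachState(x0, bleach_fraction, stochastic = FALSE)
  w <- visibleWeights(net@species)
  rhs <- function(t, y, parms) list(networkRhs(net, ps, y))
  tEnd <- 40 * 3600
  times <- seq(0, tEnd, by = 60)
  sol <- deSolve::ode(y = x0, times = times, func = rhs, parms = NULL)
  vis <- drop(as.matrix(sol[, -1]) %*% w)
  v0 <- vis[1]
  vInf <- tail(vis, 1)
  target <- v0 + 0.5 * (vInf - v0)
  idx <- which(vis >= target)[1]
  if (is.na(idx)) return(Inf)
  if (idx == 1) return(0)
  approx(vis[(idx - 1):idx], times[(idx - 1):idx], xout = target)$y
}
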