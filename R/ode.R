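#' Mass-action rate equations of a switch variant
#'
#' Mean-field time derivatives of the species counts: promoter occupancies
#' are treated as continuous fractions, every other species as a continuous
#' copy number.  This is exactly `t(S) %*% a(x)` for the variant's
#' [ReactionNetwork], i.e. the deterministic rate equations of the model.
#'
#' @param state Named continuous state (promoter species in `[0, 1]`).
#' @param params A [ParameterSet].
#' @param variant Model variant tag.
#' @param t Time (s), for protocol overrides.
#' @param protocol Optional [Protocol].
#' @return Named vector of time derivatives.
#' @export
odeRhs <- function(state, params, variant, t = 0, protocol = NULL) {
  net <- buildNetwork(variant, params)
  setNames(networkRhs(net, params, state, t, protocol), net@species)
}

# conservation ledgers of a species layout: list of species groups whose
# total copy number is invariant
promoterLedgers <- function(species) {
  led <- list(own = intersect(c("O", "OC", "OC2", "OH", "OHC", "OCd"), species),
              target = intersect(c("OTf", "OTC", "OTCd"), species),
              reporter = intersect(c("PO", "POC", "POCd"), species))
  led[vapply(led, length, 0L) > 1L]
}

# Dynamical Jacobian eigenvalues at a state: the full Jacobian of the
# mass-action RHS restricted to the tangent space of the promoter-ledger
# conservation laws (whose structural zero modes would otherwise mask the
# leading eigenvalue).
dynamicalEigen <- function(net, params, state) {
  f <- function(x) networkRhs(net, params, setNames(x, net@species))
  J <- pracma::jacobian(f, unname(state))
  led <- promoterLedgers(net@species)
  if (length(led)) {
    N <- vapply(led, function(g) as.numeric(net@species %in% g),
                numeric(length(net@species)))
    B <- qr.Q(qr(N), complete = TRUE)[, -(seq_len(ncol(N))), drop = FALSE]
    J <- t(B) %*% J %*% B
  }
  eigen(J, only.values = TRUE)$values
}

#' Fixed points of the deterministic switch
#'
#' Reduces the fixed-point problem to one dimension in the free selector
#' count `x`: at stationarity the promoter occupancies, free HD-TF and mRNA
#' are explicit functions of `x`, leaving the scalar protein balance
#' `fC * M_ss(x) - bC * x = 0`.  Roots are located by sign-change scan on a
#' log-spaced grid and polished by bisection, then classified by the leading
#' eigenvalue of the Jacobian restricted to the conservation manifold.
#'
#' The origin of the non-cooperative model is reported as `"half-stable"`:
#' it is a boundary equilibrium that is invariant (no expression can start
#' from nothing) yet is left by the flow after any positive perturbation —
#' a single mRNA suffices to drive the system back to the ON branch.
#'
#' @param params A [ParameterSet].
#' @param variant Model variant tag.
#' @param gridN Points in the sign-change scan.
#' @param tol Relative root tolerance.
#' @return List of fixed points, each a list with `state` (named continuous
#'   state), `C_free`, `C_total`, `M`, `stability` ("stable", "unstable" or
#'   "half-stable") and `leadingEigenvalue`.
#' @examples
#' fps <- findFixedPoints(publishedParams("unstable4B"), "noncoop")
#' vapply(fps, `[[`, "", "stability")
#' @export
findFixedPoints <- function(params, variant, gridN = 400, tol = 1e-10) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  fC <- rateOf(params, "fC")
  bC <- rateOf(params, "bC")
  bM <- rateOf(params, "bM")
  fM0 <- rateOf(params, "fM0", 0)
  mSS <- function(x) {
    h <- hFree(x, params, variant)
    occ <- promoterOccupancy(x, params, variant, h)
    m <- rateOf(params, "fM") * occ$productive + fM0
    if (variant %in% c("hd2a", "hd2b"))
      m <- m + rateOf(params, "fM_H") * occ$theta[["OH"]]
    m / bM
  }
  g <- function(x) fC * mSS(x) - bC * x
  mMax <- (rateOf(params, "fM") + fM0 +
             if (variant %in% c("hd2a", "hd2b")) rateOf(params, "fM_H") else 0) / bM
  xMax <- 1.2 * fC * mMax / bC + 1
  grid <- c(0, 10^seq(log10(xMax) - 8, log10(xMax), length.out = gridN))
  gv <- vapply(grid, g, 0)
  roots <- numeric(0)
  if (abs(gv[1]) < tol) roots <- 0
  for (i in seq_len(length(grid) - 1)) {
    if (i == 1 && gv[1] == 0) next
    if (gv[i] == 0 && i > 1) { roots <- c(roots, grid[i]); next }
    if (gv[i] * gv[i + 1] < 0)
      roots <- c(roots, uniroot(g, grid[c(i, i + 1)],
                                tol = tol * max(1, grid[i + 1]))$root)
  }
  roots <- sort(unique(roots))
  if (!length(roots))
    stop("no fixed point found; sign scan over x in [0, ", signif(xMax, 3),
         "] gave values ", paste(signif(range(gv), 3), collapse = " .. "))
  net <- buildNetwork(variant, params)
  lapply(roots, function(x) {
    st <- assembleState(net, params, variant, x)
    ev <- dynamicalEigen(net, params, st)
    lead <- max(Re(ev))
    # interior points: the reduced scalar balance g(x) classifies exactly
    # (these cascades are monotone, so the nullcline crossing decides);
    # the Jacobian eigenvalue is kept as a report but is numerically
    # unreliable when the slowest rate is tiny
    h <- max(1e-6 * xMax, 1e-9, 1e-6 * x)
    gp <- (g(x + h) - g(max(x - h, 0))) / (h + min(h, x))
    stability <-
      if (x < tol * xMax) {           # boundary equilibrium at the origin
        if (abs(lead) < 1e-8) "half-stable"
        else if (lead < 0) "stable"
        else "half-stable"            # invariant boundary, unstable inward
      } else if (abs(gp) < 1e-14) "half-stable"
      else if (gp < 0) "stable"
      else "unstable"
    w <- che1Weights(net@species)
    list(state = st, C_free = x,
         C_total = sum(w * st), M = st[["M"]],
         stability = stability, leadingEigenvalue = lead)
  })
}

# free HD-TF copy number as a function of free selector x
hFree <- function(x, params, variant) {
  if (!grepl("^hd", variant)) return(0)
  if (variant %in% c("hd1a", "hd2a")) {
    if (is.na(params@H0)) stop("constitutive HD variant needs H0")
    params@H0
  } else {
    rateOf(params, "fH") * x / rateOf(params, "bH")
  }
}

# continuous stationary state at free selector count x
assembleState <- function(net, params, variant, x) {
  h <- hFree(x, params, variant)
  occ <- promoterOccupancy(x, params, variant, h)
  fO <- rateOf(params, "fO")
  bT <- rateOf(params, "bT")
  thT <- fO * x / (fO * x + bT)
  sp <- net@species
  st <- setNames(numeric(length(sp)), sp)
  for (s in names(occ$theta)) if (s %in% sp) st[s] <- occ$theta[[s]]
  if ("O" %in% sp)
    st["O"] <- 1 - sum(st[intersect(c("OC", "OC2", "OH", "OHC"), sp)])
  st["M"] <- mStationary(params, variant, occ)
  st["C"] <- x
  if ("OTC" %in% sp) st["OTC"] <- params@NT * thT
  if ("OTf" %in% sp) st["OTf"] <- params@NT * (1 - thT)
  if ("H" %in% sp) st["H"] <- h
  if ("PO" %in% sp) {
    st["POC"] <- thT
    st["PO"] <- 1 - thT
    st["P"] <- rateOf(params, "fP") * thT / rateOf(params, "bP")
  }
  st
}

mStationary <- function(params, variant, occ) {
  m <- rateOf(params, "fM") * occ$productive + rateOf(params, "fM0", 0)
  if (variant %in% c("hd2a", "hd2b"))
    m <- m + rateOf(params, "fM_H") * occ$theta[["OH"]]
  m / rateOf(params, "bM")
}

#' Deterministic steady-state observables
#'
#' Evaluates the requested branch of the deterministic fixed-point set and
#' returns the observables of the model: mean mRNA, free and total selector
#' protein, own-promoter occupancy and mean occupied-target count.  Constant
#' parameter overrides (e.g. the depletion-phase rates) may be supplied to
#' obtain a perturbed quasi-steady state.
#'
#' @param params A [ParameterSet].
#' @param variant Model variant tag.
#' @param branch "ON" (largest-protein stable branch) or "OFF".
#' @param overrides Optional named rates replacing the base values.
#' @return List: `M_ss`, `C_total`, `C_free`, `theta_O`, `nT_bound`,
#'   `promoter` (named occupancies), `H_free`, `stability`.
#' @examples
#' steadyStateObservables(publishedParams("unstable4B"), "noncoop")[c("M_ss", "C_total")]
#' @export
steadyStateObservables <- function(params, variant, branch = c("ON", "OFF"),
                                   overrides = NULL) {
  branch <- match.arg(branch)
  if (!is.null(overrides)) params <- do.call(setRates, c(list(params), as.list(overrides)))
  fps <- findFixedPoints(params, variant)
  ctot <- vapply(fps, `[[`, 0, "C_total")
  fp <- if (branch == "ON") {
    cand <- fps[vapply(fps, function(f) f$stability != "unstable", TRUE)]
    if (!length(cand)) cand <- fps
    cand[[which.max(vapply(cand, `[[`, 0, "C_total"))]]
  } else fps[[which.min(ctot)]]
  if (branch == "ON" && fp$C_total <= 0)
    stop("no ON fixed point exists at these parameters")
  st <- fp$state
  sp <- names(st)
  own <- intersect(c("OC", "OC2", "OH", "OHC"), sp)
  h <- hFree(fp$C_free, params, variant)
  occ <- promoterOccupancy(fp$C_free, params, variant, h)
  list(M_ss = fp$M, C_total = fp$C_total, C_free = fp$C_free,
       theta_O = unname(occ$thetaO),
       nT_bound = if ("OTC" %in% sp) st[["OTC"]] else 0,
       promoter = st[own], H_free = h, stability = fp$stability)
}

#' Integrate the deterministic model
#'
#' Mean-field time course under an optional protocol (piecewise-constant
#' overrides are honoured between their window boundaries).
#'
#' @param params A [ParameterSet].
#' @param variant Model variant tag.
#' @param state0 Named initial state (defaults to the ON fixed point).
#' @param times Output times (s).
#' @param protocol Optional [Protocol] (overrides only).
#' @return deSolve matrix: time column plus one column per species.
#' @export
deterministicTrajectory <- function(params, variant, times, state0 = NULL,
                                    protocol = NULL) {
  net <- buildNetwork(variant, params)
  if (is.null(state0)) state0 <- onStateVector(net, params, continuous = TRUE)
  f <- function(t, y, parms)
    list(networkRhs(net, params, setNames(y, net@species), t, protocol))
  deSolve::ode(y = setNames(asStateVector(net, state0), net@species),
               times = times, func = f, parms = NULL, method = "lsoda")
}

#' Required ON-state lifetime for reliable fate maintenance
#'
#' If spontaneous ON-to-OFF switching is a Poisson process with rate `r`,
#' the fraction of animals switching within a lifetime `T` stays below
#' `phi` when `r < -ln(1 - phi)/T`, i.e. the mean ON-state lifetime must
#' exceed `T / (-ln(1 - phi))` (approximately `T/phi` for small `phi`).
#'
#' With `phi = 1e-6` and `T` = 2 weeks this bound evaluates to about
#' 3.8e4 years.  A published figure of 2.3e5 years is sometimes quoted for
#' the same inputs; it does not follow from the stated formula, so this
#' function implements the formula as written and leaves the discrepancy
#' documented here.
#'
#' @param phi Acceptable switching probability per lifetime, in (0, 1).
#' @param T Organism lifetime (s).
#' @return List of class "LifetimeRequirement": `phi`, `T`, `bound` (s),
#'   `bound_years`, `approx` (small-phi form `T/phi`, s).
#' @examples
#' requiredOnLifetime(1e-6, 14 * 86400)$bound_years # ~3.8e4
#' @export
requiredOnLifetime <- function(phi, T) {
  if (phi <= 0 || phi >= 1) stop("phi must lie in (0, 1)")
  if (T <= 0) stop("lifetime T must be positive")
  bound <- T / (-log1p(-phi))
  structure(list(phi = phi, T = T, bound = bound,
                 bound_years = bound / (365.25 * 86400),
                 approx = T / phi),
            class = "LifetimeRequirement")
}
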