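#' Normalize heat-shock induction counts
#'
#' Rescales raw per-cell mRNA counts to the unit interval spanned by the
#' uninduced control mean and the mean right after induction:
#' `n(t) = (N(t) - N_control) / (N_HS - N_control)`.
#'
#' @param N_t Raw counts (vector).
#' @param N_control Mean count without induction.
#' @param N_HS Mean count at the first post-induction time point.
#' @return Normalized values (0 = control level, 1 = induced level).
#' @examples
#' normalizeInductionCounts(15, 5, 25) # 0.5
#' @export
normalizeInductionCounts <- function(N_t, N_control, N_HS) {
  if (N_HS == N_control) stop("N_HS must differ from N_control")
  (N_t - N_control) / (N_HS - N_control)
}

#' Fit an exponential decay to a normalized chase series
#'
#' Least-squares fit of `exp(-a * t)` to normalized counts (plateau fixed
#' at 0 — the normalization already removes the control level).  The series
#' is first averaged per time point; the confidence interval is obtained by
#' resampling animals within time points and refitting.
#'
#' @param times Time of each measurement (s).
#' @param values Normalized values (same length; several animals may share
#'   a time point).
#' @param nBoot Bootstrap replicates for the CI.
#' @param level Confidence level.
#' @return List of class "DecayFit": `rate` (s^-1), `half_life` (s),
#'   `ci_rate`, `ci_half_life`, `residuals`, `fitted`.
#' @export
fitExponentialDecay <- function(times, values, nBoot = 500, level = 0.95) {
  stopifnot(length(times) == length(values))
  if (length(unique(times)) < 3)
    stop("need at least 3 distinct time points")
  fit1 <- function(tt, vv) {
    mt <- tapply(vv, tt, mean)
    ts <- as.numeric(names(mt))
    sse <- function(a) sum((mt - exp(-a * ts))^2)
    # increasing/flat series degrade gracefully to rate 0
    opt <- optimize(sse, c(0, 10 / max(max(ts), 1e-12)), tol = 1e-14)
    a <- opt$minimum
    if (sse(0) <= opt$objective) a <- 0
    a
  }
  a <- fit1(times, values)
  if (a == 0) warning("series does not decay; rate estimated as 0")
  ciR <- c(NA_real_, NA_real_)
  if (nBoot > 0) {
    boots <- vapply(seq_len(nBoot), function(b) {
      idx <- unlist(lapply(split(seq_along(times), times), function(ii)
        sample(ii, length(ii), replace = TRUE)))
      fit1(times[idx], values[idx])
    }, 0)
    alpha <- (1 - level) / 2
    ciR <- as.numeric(quantile(boots, c(alpha, 1 - alpha)))
  }
  fitted <- exp(-a * times)
  structure(list(rate = a, half_life = log(2) / a,
                 ci_rate = ciR, ci_half_life = rev(log(2) / ciR),
                 residuals = values - fitted, fitted = fitted,
                 nBoot = nBoot, level = level),
            class = "DecayFit")
}

#' @export
print.DecayFit <- function(x, ...) {
  cat("Exponential decay fit: rate =", signif(x$rate, 3), "s^-1, half-life =",
      signif(x$half_life / 60, 3), "min\n")
  cat(sprintf("%.0f%% CI (half-life): %.3g - %.3g min\n", 100 * x$level,
              x$ci_half_life[1] / 60, x$ci_half_life[2] / 60))
  invisible(x)
}

#' Fit fluorescence recovery after photobleaching
#'
#' Fits `R(t) = f/b + (x0 - f/b) * exp(-b * t)` to each recovery trace by
#' nonlinear least squares (`t = 0` is the first post-bleach sample, `x0`
#' the intensity there, `f` the effective production term and `b` the
#' recovery rate reporting protein turnover).  The population half-life is
#' the mean of the per-trace `ln(2)/b`, with a t-interval across traces.
#'
#' @param times Sample times (s), shared by all traces.
#' @param intensities Numeric vector (one trace) or matrix with one column
#'   per trace.
#' @param level Confidence level for the population interval.
#' @return List of class "FRAPFit": `perTrace` (data.frame x0, f, b,
#'   half_life), `half_life` (population mean, s), `ci_half_life`, `rate`.
#' @export
fitFrapRecovery <- function(times, intensities, level = 0.95) {
  ints <- as.matrix(intensities)
  stopifnot(nrow(ints) == length(times))
  fits <- lapply(seq_len(ncol(ints)), function(j) {
    y <- ints[, j]
    plateau0 <- mean(tail(y, max(2, length(y) %/% 4)))
    b0 <- log(2) / max(times[length(times)] / 3, 1e-9)
    # fitted in the well-scaled (x0, plateau, b) parameterization;
    # the production term is f = plateau * b
    fit <- minpack.lm::nlsLM(
      y ~ pl + (x0 - pl) * exp(-b * t),
      data = list(y = y, t = times),
      start = list(x0 = y[1], pl = plateau0, b = b0),
      lower = c(x0 = -Inf, pl = -Inf, b = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(fit)
    c(x0 = unname(cf["x0"]), f = unname(cf["pl"] * cf["b"]),
      b = unname(cf["b"]), half_life = log(2) / unname(cf["b"]))
  })
  per <- as.data.frame(do.call(rbind, fits))
  hl <- per$half_life
  n <- length(hl)
  ci <- if (n > 1) mean(hl) + qt(c((1 - level) / 2, (1 + level) / 2), n - 1) *
          sd(hl) / sqrt(n) else c(NA_real_, NA_real_)
  structure(list(perTrace = per, half_life = mean(hl), ci_half_life = ci,
                 rate = mean(per$b), level = level),
            class = "FRAPFit")
}

#' @export
print.FRAPFit <- function(x, ...) {
  cat("FRAP recovery fit over", nrow(x$perTrace), "trace(s): half-life =",
      signif(x$half_life / 60, 3), "min\n")
  invisible(x)
}

#' Absolute protein count from bath calibration
#'
#' Converts cellular fluorescence to molecule numbers by comparison with
#' the ambient fluorescence of a recombinant GFP bath of known
#' concentration: `count = (I_cell / I_bath) * c_bath * V * 0.6022`, with
#' the nuclear volume from the ellipsoid radii, `V = (4/3) * pi * x*y*z`,
#' and 0.6022 molecules per (nM * um^3).
#'
#' @param I_cell Background-corrected cellular fluorescence.
#' @param I_bath Bath fluorescence at concentration `c_bath`.
#' @param c_bath Bath concentration (nM).
#' @param radii Ellipsoid semi-axes x, y, z (um); set `diameters = TRUE`
#'   when full axes are supplied instead.
#' @param diameters Interpret `radii` as diameters and halve them.
#' @return Estimated molecule count.
#' @examples
#' proteinCountFromBathCalibration(1, 1, 72, c(1.062, 1.062, 0.846)) # ~173
#' @export
proteinCountFromBathCalibration <- function(I_cell, I_bath, c_bath, radii,
                                            diameters = FALSE) {
  if (I_bath <= 0) stop("bath intensity must be positive")
  if (any(radii <= 0)) stop("radii must be positive")
  if (diameters) radii <- radii / 2
  V <- 4 / 3 * pi * prod(radii)
  (I_cell / I_bath) * c_bath * V * 0.6022
}

#' Chemotaxis index
#'
#' `(animals on attractant - animals off attractant) / total`.
#'
#' @param n_on,n_off Animal counts on and off the attractant quadrants.
#' @return Index in `[-1, 1]`.
#' @examples
#' chemotaxisIndex(75, 25) # 0.5
#' @export
chemotaxisIndex <- function(n_on, n_off) {
  total <- n_on + n_off
  if (total <= 0) stop("need at least one animal")
  (n_on - n_off) / total
}
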