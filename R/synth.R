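GENERATOR_VERSION <- "1"

# deterministic per-item seed derivation below 2^31
deriveSeed <- function(seed, i) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(i)) %% 2147483647
}

newSyntheticDataset <- function(payload, truth, seed) {
  structure(list(payload = payload, truth = truth, seed = seed,
                 generator_version = GENERATOR_VERSION),
            class = "SyntheticDataset")
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat("SyntheticDataset (generator v", x$generator_version, ", seed ",
      x$seed, ")\n", sep = "")
  utils::str(x$truth, give.attr = FALSE)
  invisible(x)
}

#' Synthetic heat-shock mRNA chase
#'
#' Emulates the induction-chase design used to measure mRNA stability:
#' per-animal transcript counts start at an induced level and decay
#' exponentially back to baseline, `mean(t) = baseline +
#' (induced - baseline) * exp(-t * ln2 / halfLife)`, with Poisson counting
#' noise (or Gaussian noise of sd `noiseSd`), clipped at zero and rounded
#' to integers.  Control animals at the baseline level are included for the
#' normalization step.
#'
#' @param nAnimals Animals per time point.
#' @param trueHalfLife True mRNA half-life (s).
#' @param baseline Resting transcript count (control level).
#' @param inducedLevel Mean count at the first post-induction time point.
#' @param timepoints Chase sampling times (s), increasing, first = 0.
#' @param noise "poisson" or a Gaussian sd.
#' @param nControl Control animals.
#' @param seed Integer seed.
#' @return A "SyntheticDataset" whose payload is a data.frame
#'   (`animal_id`, `t_seconds`, `count`, `group`).
#' @export
genDecayChase <- function(nAnimals = 10, trueHalfLife = 17 * 60,
                          baseline = 6, inducedLevel = 24,
                          timepoints = seq(0, 4) * 17 * 60,
                          noise = "poisson", nControl = 10, seed = 1) {
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be increasing")
  set.seed(seed)
  mean_t <- baseline + (inducedLevel - baseline) *
    exp(-timepoints * log(2) / trueHalfLife)
  draw <- function(mu, n) {
    if (identical(noise, "poisson")) rpois(n, mu)
    else if (is.numeric(noise) && noise == 0) round(rep(mu, n))
    else pmax(0, round(rnorm(n, mu, noise)))
  }
  chase <- do.call(rbind, lapply(seq_along(timepoints), function(i)
    data.frame(animal_id = paste0("t", i, "_a", seq_len(nAnimals)),
               t_seconds = timepoints[i],
               count = draw(mean_t[i], nAnimals), group = "chase")))
  ctrl <- data.frame(animal_id = paste0("ctrl_a", seq_len(nControl)),
                     t_seconds = NA_real_,
                     count = draw(baseline, nControl), group = "control")
  newSyntheticDataset(rbind(chase, ctrl),
                      list(half_life = trueHalfLife,
                           rate = log(2) / trueHalfLife,
                           baseline = baseline, induced = inducedLevel,
                           mean_curve = mean_t),
                      seed)
}

#' Fit the decay stage of a synthetic (or real) chase table
#'
#' Normalizes the chase counts with the control mean and the first-time-
#' point mean, then runs [fitExponentialDecay()].
#'
#' The confidence interval resamples animals through the whole pipeline —
#' control mean, induced mean and fit — so normalization uncertainty is
#' propagated.
#'
#' @param tab data.frame with columns `t_seconds`, `count`, `group`
#'   (levels "chase"/"control"), as produced by [genDecayChase()].
#' @param nBoot Bootstrap replicates.
#' @param level Confidence level.
#' @return A "DecayFit".
#' @export
fitDecayChaseTable <- function(tab, nBoot = 500, level = 0.95) {
  fitOnce <- function(tb) {
    ctrl <- mean(tb$count[tb$group == "control"])
    ch <- tb[tb$group == "chase", ]
    t0 <- min(ch$t_seconds)
    nhs <- mean(ch$count[ch$t_seconds == t0])
    norm <- normalizeInductionCounts(ch$count, ctrl, nhs)
    fitExponentialDecay(ch$t_seconds - t0, norm, nBoot = 0)
  }
  fit <- fitOnce(tab)
  strata <- ifelse(tab$group == "control", "control", tab$t_seconds)
  boots <- vapply(seq_len(nBoot), function(b) {
    idx <- unlist(lapply(split(seq_len(nrow(tab)), strata), function(ii)
      sample(ii, length(ii), replace = TRUE)))
    fitOnce(tab[idx, ])$rate
  }, 0)
  alpha <- (1 - level) / 2
  fit$ci_rate <- as.numeric(quantile(boots, c(alpha, 1 - alpha)))
  fit$ci_half_life <- rev(log(2) / fit$ci_rate)
  fit$nBoot <- nBoot
  fit$level <- level
  fit
}

#' Synthetic fluorescence-recovery traces
#'
#' Draws recovery traces from the exponential model
#' `R(t) = plateau + (x0 - plateau) * exp(-b t)` with
#' `x0 = x0Fraction * plateau`, `b = ln2 / trueHalfLife`, plus additive
#' Gaussian noise, emulating the photobleaching design (bleach to ~20%,
#' sample every 20-30 min for ~3 h).
#'
#' @param x0Fraction Post-bleach intensity as a fraction of the plateau.
#' @param plateau Recovered intensity (arbitrary units).
#' @param trueHalfLife True recovery half-life (s).
#' @param sampleInterval Sampling interval (s).
#' @param duration Trace duration (s).
#' @param noiseSd Gaussian noise sd (intensity units).
#' @param nTraces Number of traces.
#' @param seed Integer seed (per-trace seeds derived deterministically).
#' @return A "SyntheticDataset" whose payload is a list `times`,
#'   `intensities` (matrix, one column per trace).
#' @export
genFrapTrace <- function(x0Fraction = 0.2, plateau = 1,
                         trueHalfLife = 83 * 60, sampleInterval = 20 * 60,
                         duration = 3 * 3600, noiseSd = 0.03, nTraces = 6,
                         seed = 1) {
  times <- seq(0, duration, by = sampleInterval)
  b <- log(2) / trueHalfLife
  x0 <- x0Fraction * plateau
  model <- plateau + (x0 - plateau) * exp(-b * times)
  ints <- vapply(seq_len(nTraces), function(j) {
    set.seed(deriveSeed(seed, j))
    model + rnorm(length(times), 0, noiseSd)
  }, numeric(length(times)))
  newSyntheticDataset(list(times = times, intensities = ints),
                      list(half_life = trueHalfLife, rate = b, x0 = x0,
                           plateau = plateau, noise_sd = noiseSd),
                      seed)
}

#' Synthetic single-molecule FISH stack
#'
#' Builds a 3D image stack of diffraction-limited Gaussian spots on a noisy
#' uniform background.  Spot centres are rejection-sampled to honour a
#' minimum pairwise separation and an edge margin; ground-truth coordinates
#' are stored with the stack.  Intensity is the spot's peak amplitude above
#' background, so `intensity / noiseSd` is the peak signal-to-noise ratio.
#'
#' @param nSpots Number of spots.
#' @param psfSigma Point-spread sigma in voxels (scalar or x, y, z).
#' @param intensity Peak amplitude above background.
#' @param background Constant background level.
#' @param noiseSd Gaussian noise sd.
#' @param stackShape Dimensions (x, y, z) in voxels.
#' @param minSeparation Minimum centre-to-centre distance (voxels).
#' @param seed Integer seed.
#' @return A "SyntheticDataset" whose payload is the 3D array; truth holds
#'   the coordinates.
#' @export
genSmfishStack <- function(nSpots = 7, psfSigma = 1.3, intensity = 5,
                           background = 10, noiseSd = 1,
                           stackShape = c(40, 40, 16), minSeparation = NULL,
                           seed = 1) {
  psfSigma <- rep(psfSigma, length.out = 3)
  if (is.null(minSeparation)) minSeparation <- 4 * max(psfSigma)
  set.seed(seed)
  margin <- pmin(3 * psfSigma + 1, stackShape / 4)
  centres <- matrix(0, 0, 3)
  tries <- 0
  while (nrow(centres) < nSpots) {
    if ((tries <- tries + 1) > 10000)
      stop("cannot place spots at this separation; enlarge the stack")
    pt <- margin + runif(3) * (stackShape - 2 * margin)
    if (nrow(centres) == 0 ||
        all(sqrt(rowSums(sweep(centres, 2, pt)^2)) >= minSeparation))
      centres <- rbind(centres, pt)
  }
  stack <- array(background, stackShape)
  if (nSpots > 0) {
    gx <- seq_len(stackShape[1]); gy <- seq_len(stackShape[2])
    gz <- seq_len(stackShape[3])
    for (s in seq_len(nrow(centres))) {
      cx <- exp(-(gx - centres[s, 1])^2 / (2 * psfSigma[1]^2))
      cy <- exp(-(gy - centres[s, 2])^2 / (2 * psfSigma[2]^2))
      cz <- exp(-(gz - centres[s, 3])^2 / (2 * psfSigma[3]^2))
      stack <- stack + intensity * outer(outer(cx, cy), cz)
    }
  }
  if (noiseSd > 0)
    stack <- stack + array(rnorm(prod(stackShape), 0, noiseSd), stackShape)
  colnames(centres) <- c("x", "y", "z")
  newSyntheticDataset(stack,
                      list(n_spots = nSpots, coordinates = centres,
                           psf_sigma = psfSigma, intensity = intensity,
                           background = background, noise_sd = noiseSd,
                           snr = intensity / max(noiseSd, 1e-12)),
                      seed)
}

#' Write or read a stack as a multi-page TIFF
#'
#' Thin wrappers over the `tiff` package (one page per z-slice, intensities
#' rescaled to `[0, 1]` on write with the scale stored in the filename
#' sidecar JSON).
#'
#' @param stack 3D array.
#' @param path Output path.
#' @return `writeStackTiff` returns the path; `readStackTiff` the array.
#' @export
writeStackTiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  lo <- min(stack); hi <- max(stack)
  pages <- lapply(seq_len(dim(stack)[3]), function(z)
    (stack[, , z] - lo) / max(hi - lo, 1e-12))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(list(min = lo, max = hi, dim = dim(stack)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeStackTiff
#' @export
readStackTiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF import")
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  arr * (meta$max - meta$min) + meta$min
}
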