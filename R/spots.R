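# Separable Gaussian convolution of a 3D array.  Truncated kernels are
# renormalised at the borders so flat backgrounds stay flat.
gaussianSmooth3d <- function(x, sigma) {
  sigma <- rep(sigma, length.out = 3)
  d <- dim(x)
  for (axis in 1:3) {
    s <- sigma[axis]
    if (s <= 0) next
    n <- d[axis]
    half <- max(1L, ceiling(3 * s))
    kk <- exp(-(seq(-half, half))^2 / (2 * s^2))
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- kk[ok] / sum(kk[ok])
    }
    perm <- c(axis, setdiff(1:3, axis))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    xp <- K %*% matrix(xp, nrow = dp[1])
    dim(xp) <- dp
    x <- aperm(xp, order(perm))
  }
  x
}

# minimum intensity along the voxelised segment between two points
lineMinimum <- function(sm, a, b) {
  n <- max(2, ceiling(2 * sqrt(sum((a - b)^2))))
  tt <- seq(0, 1, length.out = n)
  d <- dim(sm)
  vox <- vapply(tt, function(s) {
    p <- pmin(pmax(round(a + s * (b - a)), 1), d)
    sm[p[1], p[2], p[3]]
  }, 0)
  min(vox)
}

# logical array of 26-neighbourhood regional maxima (>= all neighbours)
regionalMaxima3d <- function(x) {
  d <- dim(x)
  pad <- array(-Inf, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- x
  res <- array(TRUE, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- pad[(2 + dx):(d[1] + 1 + dx),
              (2 + dy):(d[2] + 1 + dy),
              (2 + dz):(d[3] + 1 + dz)]
    res <- res & (x >= nb)
  }
  res
}

#' Count diffraction-limited spots in a 3D image stack
#'
#' Single-molecule spot detection: the stack is convolved with a Gaussian
#' kernel, candidate voxels are selected by thresholding, connected
#' components (26-connectivity) become candidate spots, and components
#' containing several 3D regional intensity maxima separated by at least
#' `minSeparation` voxels are split into that many spots.  Deterministic
#' given its parameters.
#'
#' When no `threshold` is supplied an automatic one is derived from the
#' smoothed stack as `median + thresholdK * MAD`, a robust stand-in for the
#' manual thresholding used at the bench; the value used is returned.
#'
#' @param stack 3D numeric array (x, y, z).
#' @param kernelSigma Gaussian kernel sigma in voxels (scalar or per-axis).
#' @param threshold Absolute intensity threshold on the smoothed stack;
#'   `NULL` for automatic.
#' @param thresholdK Robust-SD multiplier of the automatic threshold.
#' @param minSeparation Minimum maxima separation within one component
#'   (voxels).
#' @param prominenceK Multiple of the robust noise scale that the dip
#'   between two maxima must exceed for them to count as separate spots.
#' @return List: `count`, `coordinates` (matrix x, y, z of spot maxima),
#'   `threshold`, `nComponents`.
#' @export
countSpots3d <- function(stack, kernelSigma = 1, threshold = NULL,
                         thresholdK = 5, minSeparation = 2,
                         prominenceK = 2, borderMargin = NULL) {
  stopifnot(length(dim(stack)) == 3)
  sm <- gaussianSmooth3d(stack, kernelSigma)
  noiseScale <- mad(sm)
  minProminence <- prominenceK * noiseScale
  # the renormalised kernel support shrinks at the stack border, inflating
  # smoothed noise there; peaks inside the margin are not trusted
  if (is.null(borderMargin))
    borderMargin <- ceiling(2 * max(kernelSigma))
  if (is.null(threshold))
    threshold <- median(sm) + thresholdK * noiseScale
  mask <- sm > threshold
  if (!any(mask))
    return(list(count = 0L, coordinates = matrix(numeric(0), 0, 3),
                threshold = threshold, nComponents = 0L))
  lab <- label_components_3d(as.vector(mask), dim(stack))
  ncomp <- max(lab)
  rmax <- regionalMaxima3d(sm) & mask
  coords <- matrix(0, 0, 3, dimnames = list(NULL, c("x", "y", "z")))
  count <- 0L
  for (cc in seq_len(ncomp)) {
    idx <- which(lab == cc & rmax, arr.ind = TRUE)
    if (nrow(idx) == 0) { # plateau-free fallback: brightest voxel
      vox <- which(lab == cc, arr.ind = TRUE)
      idx <- vox[which.max(sm[lab == cc]), , drop = FALSE]
    }
    ints <- sm[idx]
    ord <- order(ints, decreasing = TRUE)
    idx <- idx[ord, , drop = FALSE]
    ints <- ints[ord]
    kept <- matrix(numeric(0), 0, 3)
    keptInt <- numeric(0)
    for (r in seq_len(nrow(idx))) {
      pt <- idx[r, ]
      if (any(pt <= borderMargin) || any(pt > dim(stack) - borderMargin))
        next
      accept <- TRUE
      if (nrow(kept) > 0) {
        dists <- sqrt(rowSums(sweep(kept, 2, pt)^2))
        if (any(dists < minSeparation)) accept <- FALSE
        else {
          # a genuine second molecule shows a clear dip towards every
          # stronger maximum; noise wrinkles on one blob do not
          for (q in seq_len(nrow(kept))) {
            saddle <- lineMinimum(sm, kept[q, ], pt)
            if (ints[r] - saddle < minProminence) { accept <- FALSE; break }
          }
        }
      }
      if (accept) { kept <- rbind(kept, pt); keptInt <- c(keptInt, ints[r]) }
    }
    coords <- rbind(coords, kept)
    count <- count + nrow(kept)
  }
  list(count = count, coordinates = coords, threshold = threshold,
       nComponents = ncomp)
}
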