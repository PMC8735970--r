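# Shared fixtures: copy-number-scaled parameter sets whose switching events
# are frequent enough for brute-force ensembles, plus small independent
# oracles used to cross-check the production code paths.

# weakly stable switch at 1/10 of the measured copy numbers
scaledUnstable <- function(factor = 10) {
  scaleParams(publishedParams("unstable4B"), factor)
}

# a very small system (1/20 copies) for brute-force-heavy property tests
tinyUnstable <- function() scaleParams(publishedParams("unstable4B"), 20)

# hand-built two-channel birth-death network: 0 -> X at f, X -> 0 at b
birthDeathNetwork <- function() {
  new("ReactionNetwork", variant = "noncoop", species = "X",
      stoich = matrix(c(1L, -1L), 2, 1),
      reactants = matrix(c(0L, 1L, 0L, 0L), 2, 2),
      rateNames = c("f", "b"), channelNames = c("birth", "death"),
      frap = FALSE)
}

# clamped-ligand promoter-binding network: OTf + (clamped C) <-> OTC;
# C enters the rate, not the state
clampedBindingNetwork <- function() {
  new("ReactionNetwork", variant = "noncoop", species = c("OTf", "OTC"),
      stoich = matrix(c(-1L, 1L, 1L, -1L), 2, 2),
      reactants = matrix(c(1L, 2L, 0L, 0L), 2, 2),
      rateNames = c("kon", "koff"), channelNames = c("bind", "unbind"),
      frap = FALSE)
}

# independent oracle for the binding equilibrium: damped fixed-point
# iteration on the conservation relation (no root solver involved)
bindingEquilibriumOracle <- function(C_total, fO, bO, bT, NT,
                                     iters = 2000, damp = 0.5) {
  x <- C_total
  for (i in seq_len(iters)) {
    thO <- fO * x / (fO * x + bO)
    thT <- fO * x / (fO * x + bT)
    xNew <- C_total - NT * thT - thO
    x <- damp * x + (1 - damp) * max(xNew, 0)
  }
  list(C_free = x, theta_O = fO * x / (fO * x + bO))
}

# batch-means standard error for autocorrelated series
batchSE <- function(x, nBatch = 20) {
  n <- length(x)
  bs <- floor(n / nBatch)
  means <- vapply(seq_len(nBatch), function(i)
    mean(x[((i - 1) * bs + 1):(i * bs)]), 0)
  sd(means) / sqrt(nBatch)
}
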