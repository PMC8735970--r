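---
title: "Models and methods behind SelectorSwitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind SelectorSwitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SelectorSwitch)
```

# The biological question and the model

Terminal selectors maintain neuronal identity for the lifetime of the
animal by activating their own gene together with hundreds of cell-type
genes. `SelectorSwitch` models this single-input module for the ASE-neuron
selector CHE-1: one selector gene promoter (`O`), `NT` identical target
promoters (500 or 1000), selector mRNA (`M`) and selector protein (`C`).
The protein binds any promoter site at the diffusion-limited rate
`fO = 4*pi*sigma*D/V_C` (0.03 s^-1 per molecule-site pair for a 10-nm
site, D = 1 um^2/s and a 4-um^3 nucleus) and dissociates at `bO` from its
own promoter and `bT` from targets, the only unconstrained rates. The
occupied own promoter is transcribed at `fM`; mRNA decays at `bM`,
translates at `fC`, and *free* protein decays at `bC` — promoter-bound
selector is protected, which is what the measured `fC*M/C_free` ratio
implies for the printed `bC`. All rates are per second, copy numbers are
integer molecule counts, and bimolecular rates are already volume-scaled.

Three families of variants are implemented as mass-action reaction
networks (`buildNetwork()`):

* **non-cooperative** (`noncoop`): monomer binding; the deterministic
  system has an ON fixed point plus a *half-stable* boundary state at the
  origin — the empty state is invariant, but a single mRNA molecule is
  enough to drive the system back ON. This switch is turned off only by
  molecular noise.
* **cooperative** (`coop`): sequential assembly of a promoter dimer
  (`b1`, `b2`); transcription only from the doubly bound promoter, giving
  genuine bistability (two stable fixed points flanking an unstable one).
* **homeodomain co-factor models** (`hd1a/b`, `hd2a/b`): a second
  transcription factor `H` binds the selector promoter (`fO_H`). In
  Model 1 it acts purely through affinity — the joint complex dissociates
  at the slow `bO_s << bO` — while in Model 2 it drives transcription on
  its own (`fM_H`). The `b` variants express `H` proportionally to the
  selector (`fH`, `bH`); the `a` variants clamp free `H` at `H0`.

Promoter configurations are represented as species counts, so every
propensity is `rate x count (x count)` and one stoichiometry-matrix
representation serves the exact simulator, the propensity oracle and the
mean-field rate equations (`odeRhs()` is literally `t(S) %*% a(x)`).

## Parameter derivation

`deriveParams()` reproduces the published derivation chain: `bM` is the
inverse of the measured 20-min mRNA mean lifetime (`1/1200` s^-1 is used
internally; the printed `0.00083` is its 2-significant-figure form, and
deriving from the rounded value visibly misses the printed transcription
rate of the stable switch); the binding equilibrium distributes the
measured 900 protein copies over free, own-promoter and target-bound pools
(`solveBindingEquilibrium()`, a strictly monotone scalar root problem
solved to 1e-12 relative tolerance); then `fM = bM*M_ss/theta_productive`
and `bC = fC*M_ss/C_free`. Protein production and decay can instead be
calibrated against a fluorescence-recovery half-time
(`calibrateProteinRatesToFrap()`), a one-dimensional search in `bC` with
`fC` tied by the steady state, evaluated on the two-ledger
(visible/bleached) mean-field model. At the printed stable-switch pair
this deterministic recovery half-time is ~56 min rather than the measured
83 ± 20 min target; the calibration therefore promises self-consistency
(a round trip recovers a known pair to <1%), not reproduction of the
printed pair, whose exact fitting protocol is under-determined.

The constitutive co-factor variants need a free-`H` copy number that the
source never states. The default (`hdConstitutiveH0()`) matches the
selector-controlled variant of the same model, `H0 = fH*C_ss/bH` at that
variant's ON state, so promoter occupancy by `H` agrees between the
paired variants.

# Exact stochastic simulation

`gillespieRun()` implements the direct method in compiled code
(~2e7 events/s): exponential waiting times from the summed propensities,
channel choice by cumulative sum, states recorded on a uniform grid as
exact cadlag values. Perturbation protocols are piecewise-constant rate
overrides; the run is segmented at every window edge so no step crosses a
boundary. Bleach events relabel visible protein binomially at an instant.
R's RNG drives the core, so `(configuration, seed)` determines the
trajectory bit-for-bit; ensembles derive per-run seeds deterministically
from the master seed and are order-independent.

The OFF state is defined as *no selector protein anywhere and no selector
mRNA*; without basal transcription this is absorbing in the
non-cooperative model. Tau-leaping or other approximate accelerations are
deliberately absent — lifetime estimation is a rare-event problem where
exactness matters.

# Forward flux sampling

Spontaneous ON-to-OFF switching is far too rare for direct simulation at
full copy numbers, so lifetimes come from direct forward flux sampling
(`ffsRun()`, no pruning): the switching rate is the flux of trajectories
through a first interface times the product of conditional probabilities
of advancing interface by interface to OFF.

Design choices:

* **Order parameter.** Decreasing total selector protein *plus mRNA*.
  Including the transcript makes the last interface coincide exactly with
  the absorbing OFF state (the order parameter is zero iff the switch is
  OFF); since mRNA counts are an order of magnitude below the interface
  spacing this is numerically indistinguishable from total protein
  everywhere else.
* **Interface placement** (`placeInterfaces()`). A pilot run samples the
  ON basin; excursions below the basin median are extracted and the first
  interface targets the 5-10% quantile of their minima. Because the basin
  centre itself wanders on the slow protein timescale, that raw quantile
  is noisy, so it is anchored inside a corridor of robust basin moments
  (median minus 1.5-3 MAD-based standard deviations, floored at a third
  of the median); the lifetime estimate is exact for any first-interface
  choice, so the corridor only stabilises efficiency. Interfaces then
  descend in fixed steps of 20 copies; if that yields fewer than 20 or
  more than 35 interfaces the step is adjusted (with a message) to stay
  in range. The basin characterisation truncates the pilot at the first
  committed escape so a switching event cannot poison the moments.
* **Stage 0.** The flux is measured by alternating first-interface
  crossings with returns above the basin boundary (one interface step
  above the first interface); a full spontaneous switch during this stage
  restarts the walker in the ON state. Crossing states are stored and
  later stages fire shots from them, sampled with replacement, each shot
  running until the next interface or the basin boundary.
* **Errors.** Delta method on the log lifetime: Poisson variance of the
  crossing count plus independent binomial variances per stage. A stage
  with zero successes flags the result as a lower bound.
* **Transition paths.** Shots optionally record their states on a grid;
  complete ON-to-OFF paths are reconstructed by tracing stored success
  lineages backwards and are averaged per total-selector bin
  (`averageTransitionPath()`), which is how the promoter-occupancy
  signature of the target-reservoir mechanism is exposed. Bins start at
  one copy because a state with zero selector molecules has zero
  occupancy by construction.

# Scaled study systems

Full-scale lifetimes (days to >1e5 years) cannot be brute-forced, so the
stochastic validations run on *system-size-scaled* fixtures:
`scaleParams(params, k)` divides all copy numbers by `k` while preserving
occupancies and the deterministic structure (bimolecular association
rates are multiplied by `k`, per-promoter production rates and the basal
rate divided by `k`, first-order rates untouched). At 1/10 copies the
weakly stable switch lives ~1e4-1e5 s, so flux sampling can be checked
against a plain first-passage ensemble within statistical error.

What the scaled tests do *not* show: absolute lifetimes of the full-scale
system (barriers grow roughly linearly in copy number, so lifetimes grow
exponentially), and any phenomenon that depends on having many molecules
of a sparse species. The co-factor depletion experiment is the clear
example — during 50-fold depletion the Model-1 quasi-steady state holds
only ~6 mRNAs and ~11 proteins even at full copy numbers (survival of a
2-h depletion: ~92% at full scale, ~58% at half copies, ~25% at half
copies with a 4-h window), so the in-silico panel (`hdtfPanel()`) runs at
full copy numbers and keeps the windows short instead; any substantial
copy-number reduction pushes the depleted state into stochastic
extinction and destroys the resilience the experiment probes.

Problem sizes used by the default test suite: binding-equilibrium and
fixed-point checks at full scale (instantaneous); flux-sampling
validations at 1/10 and 1/20 copies with 100-200 shots per interface;
ensemble checks with 100 runs; fit-calibration checks with 100 seeded
replicates; spot-counting checks on 40x40x16 stacks.

# Deterministic analysis

`findFixedPoints()` reduces every variant to one dimension: at fixed free
selector `x`, promoter occupancies follow from detailed balance of the
promoter cycle (closed-form weights, including the co-factor ring), free
`H` from its own balance, mRNA from transcription-decay balance, leaving
the scalar protein balance `fC*M_ss(x) = bC*x`. Roots come from a
sign-change scan on a log-spaced grid polished by bisection (1e-10
relative). Interior stability is classified by the sign of the reduced
balance derivative — exact for these monotone cascades and robust when
the slowest eigenvalue is below finite-difference resolution; the full
Jacobian (restricted to the tangent space of the promoter conservation
laws) is still reported. The origin is labelled *half-stable* when it is
an invariant boundary equilibrium that the flow leaves after any positive
perturbation, matching the verbal description of the non-cooperative OFF
state.

`requiredOnLifetime()` evaluates the Poisson bound `T/(-ln(1-phi))` on
the mean ON lifetime for a switching probability `phi` per lifetime `T`.
For `phi = 1e-6` and a two-week lifetime the formula gives ~3.8e4 years;
a published figure of 2.3e5 years circulates for the same inputs and does
not follow from the stated formula. The formula is implemented as written and both
numbers are surfaced in the documentation rather than guessing the
intended arithmetic.

# Experimental quantification stages

* **mRNA chase** (`fitExponentialDecay()`, `fitDecayChaseTable()`):
  counts are normalized by the control and first-post-induction means,
  `n(t) = (N(t)-N_ctrl)/(N_HS-N_ctrl)`, and `exp(-a*t)` is fitted to the
  per-time-point means with the plateau fixed at zero (the normalization
  already removes it). Confidence intervals bootstrap animals through the
  *entire* pipeline — control mean, induced mean and fit — because
  normalization uncertainty is a visible part of the error budget at
  3-4 post-induction time points.
* **FRAP** (`fitFrapRecovery()`): per-trace nonlinear least squares of
  `R(t) = f/b + (x0 - f/b) e^{-bt}`; the population half-life is the mean
  of per-trace `ln2/b` with a t-interval, matching the per-curve fitting
  described for the bench data. Rates are invariant to intensity
  rescaling.
* **Absolute protein counts** (`proteinCountFromBathCalibration()`):
  `(I_cell/I_bath) * c_bath * V * 0.6022` molecules per nM·um^3, with the
  nuclear volume from ellipsoid radii `V = (4/3)*pi*x*y*z` (a flag
  converts diameters).
* **Spot counting** (`countSpots3d()`): Gaussian smoothing, thresholding,
  26-connected components, then splitting components on 3D regional
  maxima. The smoothing kernel defaults slightly *below* the optical PSF
  (1.0 vs ~1.3 voxels in the synthetic data): matched filtering maximises
  peak SNR but flattens close pairs, and the narrower kernel keeps both
  maxima of a 4-sigma pair while still suppressing voxel noise. The
  manual threshold of the bench workflow is replaced by
  `median + k*MAD` of the smoothed stack (robust to the spots themselves,
  k = 5 by default, always reported). Two further guards reflect how the
  detector fails otherwise: maxima within the kernel support of the stack
  border are discarded (border renormalisation inflates smoothed noise
  there), and two maxima in one component only count as two molecules if
  the intensity dip along the line between them exceeds twice the robust
  noise scale — noise wrinkles on a single blob do not produce such a dip.
* **Chemotaxis** (`chemotaxisIndex()`): `(on - off)/total`.

# Synthetic data

The generators (`genDecayChase()`, `genFrapTrace()`, `genSmfishStack()`)
emulate the statistical structure each stage assumes — Poisson counting
noise for transcript counts, Gaussian noise for fluorescence intensities
and camera voxels, diffraction-limited Gaussian spots with a minimum
pairwise separation — with the ground truth always stored beside the
payload and every output a bit-reproducible function of its seed.
Defaults follow the study conditions: 17-min mRNA half-life with counts
falling from 24 to 6 per cell at ~17-min sampling; recovery to a plateau
from a 20% post-bleach level with an 83-min half-life sampled every
20 min for 3 h; spot SNR of 5 at 4-sigma separation. They do not emulate
autofluorescence, tissue scattering, spectral bleed-through or
camera-specific noise, so passing round trips demonstrate estimator
correctness under the assumed noise models, not performance on raw
micrographs.

# Known limitations

* The mean-field promoter treatment (continuous occupancies) is exact for
  the rate equations printed in the source but ignores promoter-state
  noise in deterministic summaries; all stochastic claims use the exact
  simulator instead.
* Lifetime error bars assume independent stages; correlations between
  stored configurations (finite stage-0 samples, resampling with
  replacement) are not propagated and make the reported log-SE mildly
  optimistic.
* The `a`-variant co-factor models clamp free `H`, ignoring fluctuations
  of a constitutively expressed factor.
* Spatial effects (nuclear sub-compartments, local rebinding) are outside
  the model: binding is well-mixed with a volume-scaled rate.
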