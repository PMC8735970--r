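#' @import methods
#' @importFrom stats uniroot optimize rexp rpois rnorm runif rbinom setNames
#'   median mad quantile sd var coef qt qnorm nls predict approx
#' @importFrom utils head tail modifyList
#' @useDynLib SelectorSwitch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' ParameterSet: kinetic rates and copy-number constants of a switch model
#'
#' Holds every rate constant of the switch models (units: per second, with
#' bimolecular association rates already divided by the nuclear volume so they
#' apply directly to molecule counts) together with the target-promoter count
#' `NT` and, for constitutive co-factor variants, the clamped free co-factor
#' copy number `H0`.
#'
#' Recognised rate symbols: `fO` (selector association with any promoter
#' site), `bO` (dissociation from the selector's own promoter,
#' non-cooperative), `b1`, `b2` (first/second dissociation, cooperative),
#' `bT` (dissociation from target promoters), `fM` (transcription from a
#' productive promoter), `bM` (mRNA decay), `fC` (translation per mRNA),
#' `bC` (decay of free selector protein), reporter rates `fP`, `bP`,
#' and homeodomain co-factor (HD-TF) rates `fO_C`, `fO_H`, `bO_s`, `fM_H`,
#' `fM0`, `fH`, `bH`.
#'
#' @slot rates Named numeric vector of non-negative rate constants (s^-1).
#' @slot NT Number of identical target promoters (>= 1).
#' @slot H0 Clamped free HD-TF copy number for constitutive variants
#'   (`NA` when unused).
#' @seealso [paramSet()], [publishedParams()], [scaleParams()]
#' @export
setClass("ParameterSet",
  representation(rates = "numeric", NT = "numeric", H0 = "numeric"),
  prototype(rates = numeric(0), NT = 500, H0 = NA_real_))

setValidity("ParameterSet", function(object) {
  msgs <- character(0)
  r <- object@rates
  if (length(r) && (is.null(names(r)) || any(!nzchar(names(r)))))
    msgs <- c(msgs, "all rates must be named")
  if (any(!is.finite(r)) || any(r < 0))
    msgs <- c(msgs, "all rates must be finite and >= 0")
  if (length(object@NT) != 1L || !is.finite(object@NT) || object@NT < 1)
    msgs <- c(msgs, "NT must be a single value >= 1")
  if (all(c("bO_s", "bO") %in% names(r)) && r[["bO_s"]] > r[["bO"]])
    msgs <- c(msgs, "cooperative co-factor dissociation bO_s must not exceed bO")
  if (length(msgs)) msgs else TRUE
})

#' Protocol: timed parameter overrides and bleach events
#'
#' A perturbation protocol is a list of piecewise-constant rate overrides,
#' each `(tStart, tEnd, param, value)`, plus optional instantaneous bleach
#' events `(t, fraction)` that relabel the stated fraction of visible
#' selector protein (free and promoter-bound) as photobleached ("dark").
#' Outside every window the base [ParameterSet] applies.
#'
#' @slot overrides data.frame with columns tStart, tEnd, param, value.
#' @slot bleaches data.frame with columns t, fraction.
#' @seealso [protocol()], [depletionProtocol()], [inductionProtocol()]
#' @export
setClass("Protocol",
  representation(overrides = "data.frame", bleaches = "data.frame"),
  prototype(
    overrides = data.frame(tStart = numeric(0), tEnd = numeric(0),
                           param = character(0), value = numeric(0),
                           stringsAsFactors = FALSE),
    bleaches = data.frame(t = numeric(0), fraction = numeric(0))))

setValidity("Protocol", function(object) {
  ov <- object@overrides
  msgs <- character(0)
  if (!all(c("tStart", "tEnd", "param", "value") %in% names(ov)))
    msgs <- c(msgs, "overrides needs columns tStart, tEnd, param, value")
  else if (nrow(ov) && any(ov$tStart > ov$tEnd))
    msgs <- c(msgs, "override windows must have tStart <= tEnd")
  bl <- object@bleaches
  if (nrow(bl) && (any(bl$fraction < 0) || any(bl$fraction > 1)))
    msgs <- c(msgs, "bleach fractions must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' ReactionNetwork: the reaction channels of one model variant
#'
#' An ordered list of mass-action channels over an integer state vector whose
#' components are molecular species counts; promoter configurations (empty,
#' selector-bound, doubly bound, co-factor-bound, ...) are themselves species
#' so that every propensity is a rate constant times the product of at most
#' two reactant counts.
#'
#' @slot variant Model tag: one of "noncoop", "coop", "hd1a", "hd1b",
#'   "hd2a", "hd2b".
#' @slot species Character vector of species names (state-vector layout).
#' @slot stoich Integer matrix, channels x species.
#' @slot reactants Integer matrix, channels x 2, 1-based species indices with
#'   0 meaning no factor.
#' @slot rateNames Rate symbol powering each channel.
#' @slot channelNames Human-readable channel labels.
#' @slot frap TRUE when the network carries a photobleached protein ledger.
#' @seealso [buildNetwork()]
#' @export
setClass("ReactionNetwork",
  representation(variant = "character", species = "character",
                 stoich = "matrix", reactants = "matrix",
                 rateNames = "character", channelNames = "character",
                 frap = "logical"),
  prototype(frap = FALSE))

setValidity("ReactionNetwork", function(object) {
  msgs <- character(0)
  nch <- nrow(object@stoich)
  nsp <- length(object@species)
  if (ncol(object@stoich) != nsp) msgs <- c(msgs, "stoich/species mismatch")
  if (nrow(object@reactants) != nch || ncol(object@reactants) != 2L)
    msgs <- c(msgs, "reactants must be channels x 2")
  if (length(object@rateNames) != nch)
    msgs <- c(msgs, "one rate symbol per channel required")
  if (length(msgs)) msgs else TRUE
})

#' Trajectory: a sampled stochastic time course
#'
#' State snapshots of a Gillespie run on a uniform time grid, together with
#' the seed, event count and protocol that produced it.
#'
#' @slot times Sample times (s), strictly increasing.
#' @slot states Integer matrix, one row per sample, columns named by species.
#' @slot variant Model variant tag.
#' @slot seed Seed of the run.
#' @slot eventCount Number of reaction events fired.
#' @slot protocol The [Protocol] applied (possibly empty).
#' @slot exit "tmax", "absorbing" or "stopped".
#' @export
setClass("Trajectory",
  representation(times = "numeric", states = "matrix", variant = "character",
                 seed = "numeric", eventCount = "numeric",
                 protocol = "Protocol", exit = "character"))

setValidity("Trajectory", function(object) {
  msgs <- character(0)
  if (length(object@times) != nrow(object@states))
    msgs <- c(msgs, "one state row per sample time required")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msgs <- c(msgs, "sample times must be strictly increasing")
  if (any(object@states < 0)) msgs <- c(msgs, "negative copy number recorded")
  if (length(msgs)) msgs else TRUE
})

#' FFSConfig: interfaces and budgets for forward flux sampling
#'
#' @slot lambdaOn Reference ON-basin mean of the order parameter
#'   (total selector protein + mRNA).
#' @slot lambdaA Basin-return boundary (order-parameter value; shots that
#'   climb back to it are counted as failures).
#' @slot interfaces Decreasing order-parameter thresholds, the last one 0
#'   (the absorbing OFF state: no selector protein anywhere and no mRNA).
#' @slot trials Shots fired per interface.
#' @slot maxStore Stored crossing configurations per interface.
#' @slot seed Master seed.
#' @export
setClass("FFSConfig",
  representation(lambdaOn = "numeric", lambdaA = "numeric",
                 interfaces = "numeric", trials = "numeric",
                 maxStore = "numeric", seed = "numeric"))

setValidity("FFSConfig", function(object) {
  msgs <- character(0)
  ifc <- object@interfaces
  if (length(ifc) < 2) msgs <- c(msgs, "need at least two interfaces")
  if (any(diff(ifc) >= 0)) msgs <- c(msgs, "interfaces must decrease toward OFF")
  if (tail(ifc, 1) != 0) msgs <- c(msgs, "last interface must be the OFF state (0)")
  if (object@lambdaA <= ifc[1]) msgs <- c(msgs, "basin boundary must sit above the first interface")
  if (object@trials < 1) msgs <- c(msgs, "trials must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' FFSResult: flux, crossing probabilities, lifetime and transition paths
#'
#' @slot config The [FFSConfig] used.
#' @slot flux0 Crossings of the first interface per second of ON-basin time.
#' @slot nCross0 Number of first-interface crossings observed.
#' @slot p Conditional probabilities P(reach interface i+1 | at interface i).
#' @slot pErr Binomial standard errors of p.
#' @slot lifetime Mean ON-state lifetime 1/(flux0 * prod(p)) in seconds.
#' @slot lifetimeLogSE Standard error of log(lifetime) (delta method).
#' @slot lowerBoundOnly TRUE when some stage had zero successes and the
#'   lifetime is only a lower bound.
#' @slot paths List of complete ON-to-OFF transition paths (matrices of
#'   sampled states with a time column).
#' @slot species Species layout of stored states.
#' @export
setClass("FFSResult",
  representation(config = "FFSConfig", flux0 = "numeric", nCross0 = "numeric",
                 p = "numeric", pErr = "numeric", lifetime = "numeric",
                 lifetimeLogSE = "numeric", lowerBoundOnly = "logical",
                 paths = "list", species = "character"))
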