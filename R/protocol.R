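#' Build a perturbation protocol
#'
#' @param overrides data.frame with columns `tStart`, `tEnd`, `param`,
#'   `value`: the named rate is replaced by `value` for
#'   `tStart <= t < tEnd` and reverts to the base [ParameterSet] outside.
#' @param bleaches data.frame with columns `t`, `fraction`: at time `t` the
#'   stated fraction of visible selector protein is instantaneously
#'   relabelled photobleached.
#' @return A [Protocol].
#' @export
protocol <- function(overrides = NULL, bleaches = NULL) {
  empty <- data.frame(tStart = numeric(0), tEnd = numeric(0),
                      param = character(0), value = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(overrides)) overrides <- empty
  if (is.null(bleaches))
    bleaches <- data.frame(t = numeric(0), fraction = numeric(0))
  new("Protocol", overrides = overrides, bleaches = bleaches)
}

#' @describeIn protocol Transient increase of selector degradation
#'   (auxin-style depletion): `bC` is multiplied by `factor` inside the
#'   window.
#' @param params Base [ParameterSet] (supplies the resting `bC`).
#' @param tStart,tEnd Window (s).
#' @param factor Fold-increase of degradation (50 in the depletion panels).
#' @export
depletionProtocol <- function(params, tStart, tEnd, factor = 50) {
  protocol(data.frame(tStart = tStart, tEnd = tEnd, param = "bC",
                      value = factor * rateOf(params, "bC"),
                      stringsAsFactors = FALSE))
}

#' @describeIn protocol Transient selector-independent induction: the basal
#'   transcription rate `fM0` takes `value` inside the window and 0 outside.
#' @param value Basal transcription rate inside the window (s^-1).
#' @export
inductionProtocol <- function(tStart, tEnd, value) {
  protocol(data.frame(tStart = tStart, tEnd = tEnd, param = "fM0",
                      value = value, stringsAsFactors = FALSE))
}

#' @describeIn protocol Instantaneous photobleach of a fraction of visible
#'   selector protein at time `t`.
#' @param t Bleach time (s).
#' @param fraction Fraction of visible protein turned dark.
#' @export
bleachProtocol <- function(t, fraction = 0.8) {
  protocol(bleaches = data.frame(t = t, fraction = fraction))
}

#' @describeIn protocol Permanent deletion of the selector binding motif in
#'   the selector's own promoter: returns a modified [ParameterSet] with
#'   `fO_C = 0` (the motif is gone for all time; target binding is
#'   unaffected).
#' @export
motifDeletionParams <- function(params) {
  setRates(params, fO_C = 0)
}

setMethod("show", "Protocol", function(object) {
  cat("Protocol:", nrow(object@overrides), "override window(s),",
      nrow(object@bleaches), "bleach event(s)\n")
  if (nrow(object@overrides)) print(object@overrides)
  if (nrow(object@bleaches)) print(object@bleaches)
})
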