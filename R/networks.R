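MODEL_VARIANTS <- c("noncoop", "coop", "hd1a", "hd1b", "hd2a", "hd2b")

# internal channel-table builder: each row one mass-action channel,
# described by reactant species (<= 2), product species, and a rate symbol.
channelRow <- function(name, rate, from = character(0), to = character(0)) {
  list(name = name, rate = rate, from = from, to = to)
}

#' Build the reaction network of a model variant
#'
#' Assembles the full channel list of one switch variant as a mass-action
#' [ReactionNetwork].  Promoter configurations are species, so the state
#' vector is a plain vector of counts and every propensity is
#' `rate * count1 (* count2)`.
#'
#' Variants: `"noncoop"` (monomer binding to the selector's own promoter,
#' 8 core channels), `"coop"` (sequential dimer assembly, transcription only
#' from the doubly bound promoter), and four homeodomain co-factor models:
#' `"hd1a"`/`"hd1b"` (HD-TF as co-factor; joint promoter complex dissociates
#' at the slow rate `bO_s`; transcription from both selector-bound states)
#' and `"hd2a"`/`"hd2b"` (HD-TF induces transcription independently at
#' `fM_H`).  The `b` variants express HD-TF proportionally to the selector
#' (`fH`, `bH`); the `a` variants clamp free HD-TF at `H0` (it enters
#' propensities but is never consumed).
#'
#' Optional blocks: a reporter-target promoter (`fP`, `bP` present) that
#' binds like any target and emits reporter mRNA `P`; a basal transcription
#' channel when `fM0` is present; and a photobleached ("dark") protein
#' ledger (`frap = TRUE`) whose species bind, unbind, activate transcription
#' and decay exactly like visible protein but are never produced.
#'
#' @param variant One of `"noncoop"`, `"coop"`, `"hd1a"`, `"hd1b"`,
#'   `"hd2a"`, `"hd2b"`.
#' @param params A [ParameterSet] carrying every rate the variant needs
#'   (missing rates raise an error naming the symbol).
#' @param frap Add the photobleached protein ledger (supported for
#'   "noncoop").
#' @return A [ReactionNetwork].
#' @examples
#' net <- buildNetwork("noncoop", publishedParams("unstable4B"))
#' length(net@channelNames) # 8
#' @export
buildNetwork <- function(variant, params, frap = FALSE) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  r <- params@rates
  need <- function(sym) {
    if (!all(sym %in% names(r)))
      stop("variant '", variant, "' requires rate(s): ",
           paste(setdiff(sym, names(r)), collapse = ", "), call. = FALSE)
  }
  ch <- list()
  addCh <- function(...) ch[[length(ch) + 1L]] <<- channelRow(...)
  hd <- grepl("^hd", variant)
  reporter <- all(c("fP", "bP") %in% names(r))
  basal <- "fM0" %in% names(r)

  if (variant == "noncoop") {
    need(c("fO", "bO", "bT", "fM", "bM", "fC", "bC"))
    ownBind <- if ("fO_C" %in% names(r)) "fO_C" else "fO"
    addCh("own promoter binding", ownBind, c("O", "C"), "OC")
    addCh("own promoter unbinding", "bO", "OC", c("O", "C"))
    addCh("target binding", "fO", c("OTf", "C"), "OTC")
    addCh("target unbinding", "bT", "OTC", c("OTf", "C"))
    addCh("transcription", "fM", "OC", c("OC", "M"))
    addCh("mRNA decay", "bM", "M", character(0))
    addCh("translation", "fC", "M", c("M", "C"))
    addCh("protein decay", "bC", "C", character(0))
  } else if (variant == "coop") {
    need(c("fO", "b1", "b2", "bT", "fM", "bM", "fC", "bC"))
    addCh("first own-promoter binding", "fO", c("O", "C"), "OC")
    addCh("first own-promoter unbinding", "b1", "OC", c("O", "C"))
    addCh("second own-promoter binding", "fO", c("OC", "C"), "OC2")
    addCh("second own-promoter unbinding", "b2", "OC2", c("OC", "C"))
    addCh("target binding", "fO", c("OTf", "C"), "OTC")
    addCh("target unbinding", "bT", "OTC", c("OTf", "C"))
    addCh("transcription", "fM", "OC2", c("OC2", "M"))
    addCh("mRNA decay", "bM", "M", character(0))
    addCh("translation", "fC", "M", c("M", "C"))
    addCh("protein decay", "bC", "C", character(0))
  } else {
    need(c("fO", "fO_C", "fO_H", "bO", "bT", "fM", "bM", "fC", "bC"))
    model1 <- variant %in% c("hd1a", "hd1b")
    if (model1) need("bO_s") else need("fM_H")
    constitutive <- variant %in% c("hd1a", "hd2a")
    if (!constitutive) need(c("fH", "bH"))
    addCh("selector-own-promoter binding", "fO_C", c("O", "C"), "OC")
    addCh("selector-own-promoter unbinding", "bO", "OC", c("O", "C"))
    addCh("target binding", "fO", c("OTf", "C"), "OTC")
    addCh("target unbinding", "bT", "OTC", c("OTf", "C"))
    addCh("HD-TF promoter binding", "fO_H", c("O", "H"), "OH")
    addCh("HD-TF promoter unbinding", "bO", "OH", c("O", "H"))
    addCh("transcription from OC", "fM", "OC", c("OC", "M"))
    addCh("mRNA decay", "bM", "M", character(0))
    addCh("translation", "fC", "M", c("M", "C"))
    addCh("protein decay", "bC", "C", character(0))
    if (model1) {
      addCh("selector joins OH", "fO_C", c("OH", "C"), "OHC")
      addCh("selector leaves complex (slow)", "bO_s", "OHC", c("OH", "C"))
      addCh("HD-TF joins OC", "fO_H", c("OC", "H"), "OHC")
      addCh("HD-TF leaves complex (slow)", "bO_s", "OHC", c("OC", "H"))
      addCh("transcription from OHC", "fM", "OHC", c("OHC", "M"))
    } else {
      addCh("HD-TF-driven transcription", "fM_H", "OH", c("OH", "M"))
    }
    if (!constitutive) {
      addCh("HD-TF production", "fH", "C", c("C", "H"))
      addCh("HD-TF decay", "bH", "H", character(0))
    }
  }
  if (basal) addCh("basal transcription", "fM0", character(0), "M")
  if (reporter) {
    addCh("reporter promoter binding", "fO", c("PO", "C"), "POC")
    addCh("reporter promoter unbinding", "bT", "POC", c("PO", "C"))
    addCh("reporter transcription", "fP", "POC", c("POC", "P"))
    addCh("reporter mRNA decay", "bP", "P", character(0))
  }
  if (frap) {
    if (variant != "noncoop")
      stop("photobleach ledger implemented for the non-cooperative model")
    addCh("own promoter binding (dark)", "fO", c("O", "Cd"), "OCd")
    addCh("own promoter unbinding (dark)", "bO", "OCd", c("O", "Cd"))
    addCh("target binding (dark)", "fO", c("OTf", "Cd"), "OTCd")
    addCh("target unbinding (dark)", "bT", "OTCd", c("OTf", "Cd"))
    addCh("transcription (dark-bound promoter)", "fM", "OCd", c("OCd", "M"))
    addCh("protein decay (dark)", "bC", "Cd", character(0))
    if (reporter) {
      addCh("reporter promoter binding (dark)", "fO", c("PO", "Cd"), "POCd")
      addCh("reporter promoter unbinding (dark)", "bT", "POCd", c("PO", "Cd"))
      addCh("reporter transcription (dark-bound)", "fP", "POCd", c("POCd", "P"))
    }
  }

  species <- unique(unlist(lapply(ch, function(x) c(x$from, x$to))))
  # clamp free HD-TF in constitutive variants: present in propensities,
  # never changed by any channel
  clampH <- hd && variant %in% c("hd1a", "hd2a")
  nch <- length(ch)
  nsp <- length(species)
  S <- matrix(0L, nch, nsp, dimnames = list(NULL, species))
  Rx <- matrix(0L, nch, 2L)
  for (j in seq_len(nch)) {
    for (s in ch[[j]]$from) S[j, s] <- S[j, s] - 1L
    for (s in ch[[j]]$to) S[j, s] <- S[j, s] + 1L
    fr <- ch[[j]]$from
    if (length(fr) >= 1) Rx[j, 1] <- match(fr[1], species)
    if (length(fr) == 2) Rx[j, 2] <- match(fr[2], species)
  }
  if (clampH && "H" %in% species) S[, "H"] <- 0L
  new("ReactionNetwork", variant = variant, species = species, stoich = S,
      reactants = Rx, rateNames = vapply(ch, `[[`, "", "rate"),
      channelNames = vapply(ch, `[[`, "", "name"), frap = frap)
}

setMethod("show", "ReactionNetwork", function(object) {
  cat("ReactionNetwork '", object@variant, "': ",
      length(object@channelNames), " channels, ",
      length(object@species), " species",
      if (object@frap) " (photobleach ledger)", "\n", sep = "")
  cat("species:", paste(object@species, collapse = ", "), "\n")
})

# Resolve the per-channel rate constants of a network from a ParameterSet,
# applying any protocol overrides active at time t.
resolveRates <- function(network, params, t = 0, protocol = NULL) {
  r <- params@rates
  if (!is.null(protocol) && nrow(protocol@overrides)) {
    ov <- protocol@overrides
    act <- ov$tStart <= t & t < ov$tEnd
    for (i in which(act)) r[[ov$param[i]]] <- ov$value[i]
  }
  miss <- setdiff(unique(network@rateNames), names(r))
  if (length(miss))
    stop("missing rate(s): ", paste(miss, collapse = ", "), call. = FALSE)
  unname(r[network@rateNames])
}

#' Propensity vector of a network at a state
#'
#' Mass-action propensities `rate * reactant1 (* reactant2)` for every
#' channel, with protocol overrides applied at time `t`.  A total propensity
#' of zero is a valid return and identifies an absorbing state.
#'
#' @param network A [ReactionNetwork].
#' @param state Named (or layout-ordered) non-negative counts.
#' @param t Time in seconds (for protocol overrides).
#' @param protocol Optional [Protocol].
#' @param params The [ParameterSet].
#' @return Numeric vector of non-negative propensities, one per channel.
#' @export
propensityVector <- function(network, state, params, t = 0, protocol = NULL) {
  x <- asStateVector(network, state)
  k <- resolveRates(network, params, t, protocol)
  a <- k
  r1 <- network@reactants[, 1]
  r2 <- network@reactants[, 2]
  has1 <- r1 > 0
  has2 <- r2 > 0
  a[has1] <- a[has1] * x[r1[has1]]
  a[has2] <- a[has2] * x[r2[has2]]
  setNames(a, network@channelNames)
}

# Coerce named counts to the network's species layout; unnamed vectors must
# already be in layout order.
asStateVector <- function(network, state) {
  sp <- network@species
  if (is.null(names(state))) {
    if (length(state) != length(sp)) stop("state length does not match species")
    return(as.numeric(state))
  }
  x <- setNames(numeric(length(sp)), sp)
  known <- intersect(names(state), sp)
  bad <- setdiff(names(state), sp)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  x[known] <- state[known]
  unname(x)
}

# Mean-field right-hand side of a network: dX/dt = t(S) %*% a(x), the
# mass-action rate equations of the variant.
networkRhs <- function(network, params, state, t = 0, protocol = NULL) {
  a <- propensityVector(network, state, params, t, protocol)
  drop(t(network@stoich) %*% a)
}

# weights extracting total selector protein (free + every bound form,
# visible and dark) from a state vector
che1Weights <- function(species) {
  w <- setNames(numeric(length(species)), species)
  ones <- intersect(c("C", "Cd", "OC", "OTC", "OHC", "OCd", "OTCd",
                      "POC", "POCd"), species)
  w[ones] <- 1
  if ("OC2" %in% species) w["OC2"] <- 2
  w
}

# weights extracting visible (unbleached) selector protein
visibleWeights <- function(species) {
  w <- che1Weights(species)
  dark <- intersect(c("Cd", "OCd", "OTCd", "POCd"), species)
  w[dark] <- 0
  w
}

#' Total selector protein along a trajectory
#'
#' Sums free and every promoter-bound selector molecule (doubly bound
#' promoters count twice; photobleached molecules are included unless
#' `visibleOnly`).
#'
#' @param traj A [Trajectory].
#' @param visibleOnly Exclude the photobleached ledger.
#' @return Numeric vector, one value per sample time.
#' @export
totalSelector <- function(traj, visibleOnly = FALSE) {
  w <- if (visibleOnly) visibleWeights(colnames(traj@states))
       else che1Weights(colnames(traj@states))
  drop(traj@states %*% w)
}

# Deterministic ON state mapped onto a network's species layout.
# continuous = TRUE keeps fractional promoter occupancies (for ODE work);
# otherwise everything is rounded to integers and promoter ledgers are
# re-normalised to their copy numbers.
onStateVector <- function(network, params, continuous = FALSE) {
  ss <- steadyStateObservables(params, network@variant)
  sp <- network@species
  x <- setNames(numeric(length(sp)), sp)
  th <- ss$promoter          # named occupancies of the own promoter
  for (s in names(th)) if (s %in% sp) x[s] <- th[[s]]
  if ("O" %in% sp) x["O"] <- 1 - sum(x[intersect(c("OC", "OC2", "OH", "OHC"), sp)])
  x["M"] <- ss$M_ss
  x["C"] <- ss$C_free
  if ("OTC" %in% sp) x["OTC"] <- ss$nT_bound
  if ("OTf" %in% sp) x["OTf"] <- params@NT - x["OTC"]
  if ("H" %in% sp) x["H"] <- ss$H_free
  if ("PO" %in% sp) { # reporter promoter equilibrates like a target
    thT <- ss$nT_bound / params@NT
    x["POC"] <- thT
    x["PO"] <- 1 - thT
    x["P"] <- rateOf(params, "fP") * thT / rateOf(params, "bP")
  }
  if (continuous) return(x)
  xi <- round(x)
  # keep promoter ledgers at their exact copy numbers after rounding
  own <- intersect(c("O", "OC", "OC2", "OH", "OHC"), sp)
  if (length(own)) {
    xi[own] <- 0
    xi[own[which.max(x[own])]] <- 1
  }
  if ("OTf" %in% sp) xi["OTf"] <- params@NT - xi["OTC"]
  if ("PO" %in% sp) xi["PO"] <- 1 - xi["POC"]
  xi
}

# Apply a bleach event: a fraction of each visible selector pool is
# relabelled dark.  Stochastic mode draws binomially per pool; promoter-bound
# molecules move their promoter species to the dark-bound species.
bleachState <- function(state, fraction, stochastic = TRUE) {
  pools <- list(c("C", "Cd"), c("OC", "OCd"), c("OTC", "OTCd"),
                c("POC", "POCd"))
  for (p in pools) {
    if (!all(p %in% names(state))) next
    n <- state[[p[1]]]
    if (n <= 0) next
    k <- if (stochastic) rbinom(1, n, fraction) else n * fraction
    state[[p[1]]] <- state[[p[1]]] - k
    state[[p[2]]] <- state[[p[2]]] + k
  }
  state
}
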