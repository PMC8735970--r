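test_that("the non-cooperative network has exactly the 8 published channels", {
  net <- buildNetwork("noncoop", publishedParams("unstable4B"))
  expect_length(net@channelNames, 8)
  expect_setequal(net@species, c("O", "OC", "OTf", "OTC", "M", "C"))
  # reporter block adds promoter binding, unbinding, transcription, decay
  netR <- buildNetwork("noncoop", publishedParams("stable4E"))
  expect_length(netR@channelNames, 12)
  expect_true(all(c("PO", "POC", "P") %in% netR@species))
})

test_that("cooperative transcription needs the doubly bound promoter", {
  p <- paramSet(fO = 0.03, b1 = 1, b2 = 1, bT = 100, fM = 0.03,
                bM = 1 / 1200, fC = 0.027, bC = 2e-4, NT = 500)
  net <- buildNetwork("coop", p)
  st1 <- c(O = 0, OC = 1, OC2 = 0, OTf = 500, OTC = 0, M = 0, C = 100)
  a1 <- propensityVector(net, st1, p)
  expect_equal(unname(a1["transcription"]), 0)
  st2 <- c(O = 0, OC = 0, OC2 = 1, OTf = 500, OTC = 0, M = 0, C = 100)
  a2 <- propensityVector(net, st2, p)
  expect_equal(unname(a2["transcription"]), 0.03)
})

test_that("motif deletion silences the own promoter but not the targets", {
  p <- motifDeletionParams(publishedParams("hd1a"))
  net <- buildNetwork("hd1a", p)
  st <- setNames(numeric(length(net@species)), net@species)
  st[c("O", "C", "H")] <- c(1, 100, 50)
  st["OTf"] <- 500
  a <- propensityVector(net, st, p)
  expect_equal(unname(a["selector-own-promoter binding"]), 0)
  expect_equal(unname(a["selector joins OH"]), 0)
  expect_gt(unname(a["target binding"]), 0)
})

test_that("propensities follow mass action on the published rates", {
  p <- publishedParams("unstable4B", roundedBM = TRUE)
  net <- buildNetwork("noncoop", p)
  st <- c(O = 0, OC = 1, OTf = 403, OTC = 97, M = 7, C = 803)
  a <- propensityVector(net, st, p)
  expect_equal(unname(a["transcription"]), 0.0302)
  expect_equal(unname(a["mRNA decay"]), 0.00581)
  expect_equal(unname(a["target binding"]), 0.03 * 803 * 403)
  expect_equal(unname(a["protein decay"]), 0.00024 * 803)
  # the empty state without basal transcription is absorbing
  off <- c(O = 1, OC = 0, OTf = 500, OTC = 0, M = 0, C = 0)
  expect_equal(sum(propensityVector(net, off, p)), 0)
})

test_that("protocol overrides apply inside their window only", {
  p <- publishedParams("unstable4B")
  net <- buildNetwork("noncoop", p)
  prot <- depletionProtocol(p, 100, 200, factor = 50)
  st <- c(O = 0, OC = 1, OTf = 403, OTC = 97, M = 7, C = 803)
  aIn <- propensityVector(net, st, p, t = 150, protocol = prot)
  aOut <- propensityVector(net, st, p, t = 250, protocol = prot)
  expect_equal(unname(aIn["protein decay"]) / unname(aOut["protein decay"]), 50)
})

test_that("every channel conserves the promoter ledgers", {
  variants <- list(noncoop = publishedParams("unstable4B"),
                   coop = paramSet(fO = 0.03, b1 = 1, b2 = 1, bT = 100,
                                   fM = 0.03, bM = 1e-3, fC = 0.027,
                                   bC = 2e-4, NT = 500),
                   hd1b = publishedParams("hd1b"),
                   hd2b = publishedParams("hd2b"),
                   stable4E = publishedParams("stable4E"))
  for (nm in names(variants)) {
    v <- if (nm == "stable4E") "noncoop" else nm
    net <- buildNetwork(v, variants[[nm]])
    for (grp in SelectorSwitch:::promoterLedgers(net@species)) {
      sums <- rowSums(net@stoich[, grp, drop = FALSE])
      expect_true(all(sums == 0), info = paste(nm, paste(grp, collapse = "+")))
    }
  }
})

test_that("photobleached protein mirrors visible protein except in translation", {
  p <- publishedParams("unstable4B")
  net <- buildNetwork("noncoop", p, frap = TRUE)
  cn <- net@channelNames
  # every visible selector channel has a dark twin with the same rate symbol
  twins <- rbind(c("own promoter binding", "own promoter binding (dark)"),
                 c("own promoter unbinding", "own promoter unbinding (dark)"),
                 c("target binding", "target binding (dark)"),
                 c("target unbinding", "target unbinding (dark)"),
                 c("protein decay", "protein decay (dark)"))
  for (i in seq_len(nrow(twins))) {
    rv <- net@rateNames[match(twins[i, 1], cn)]
    rd <- net@rateNames[match(twins[i, 2], cn)]
    expect_equal(rv, rd, info = twins[i, 1])
  }
  # transcription also fires from the dark-bound promoter ...
  expect_true("transcription (dark-bound promoter)" %in% cn)
  # ... but translation never produces dark protein
  tj <- match("translation", cn)
  expect_equal(unname(net@stoich[tj, "Cd"]), 0)
  expect_equal(unname(net@stoich[tj, "C"]), 1)
})

test_that("configuration errors name the missing pieces", {
  expect_error(buildNetwork("noncoop", paramSet(fO = 0.03, NT = 10)), "bO")
  expect_error(buildNetwork("hd1a", paramSet(fO = 0.03, fO_C = 0.03,
                                             fO_H = 0.03, bO = 100, bT = 100,
                                             fM = 0.01, bM = 1e-3, fC = 0.02,
                                             bC = 3e-4, NT = 10)), "bO_s")
  expect_error(buildNetwork("nope", publishedParams("unstable4B")))
})
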