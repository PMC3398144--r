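test_that("panel members renormalise to unity against their own panel", {
  m <- pmsMap
  set.seed(8)
  cand <- makeReferenceCandidates(8, PopulationModel(pHybridCarrier = 0), m,
                                  NoiseModel(0.05))
  panel <- buildPanel(cand$signals, m)
  rels <- vapply(panelMembers(panel), function(id)
    normalizeSignals(cand$signals[, id], panel, m),
    numeric(nrow(probeSites(m))))
  # per-probe mean over the members is 1 by construction of the panel mean
  expect_true(all(abs(rowMeans(rels) - 1) < 0.01))
})

test_that("published signal semantics map to integer copies", {
  m <- pmsMap
  ids <- probeSites(m)$id
  rel <- setNames(rep(1, length(ids)), ids)
  rel["P_E8a"] <- 0.5    # one copy at a gene-specific probe
  rel["U_E13"] <- 0.75   # three of four at a universal probe
  rel["PP_E14"] <- 1.5   # three copies at a pseudogene-specific probe
  cc <- copyCalls(callCopyNumbers(rel, m))
  expect_identical(cc["P_E8a", "copies"], 1L)
  expect_identical(cc["U_E13", "copies"], 3L)
  expect_identical(cc["PP_E14", "copies"], 3L)
  expect_identical(cc["P_E1", "copies"], 2L)
  expect_identical(cc["U_E15", "copies"], 4L)
})

test_that("ambiguous signals abstain rather than miscall", {
  m <- pmsMap
  ids <- probeSites(m)$id
  rel <- setNames(rep(1, length(ids)), ids)
  rel["P_E8a"] <- 0.62   # 1.24 copies: > 0.2 from both 1 and 2 at band 0.1
  cc <- copyCalls(callCopyNumbers(rel, m, band = 0.1))
  expect_true(is.na(cc["P_E8a", "copies"]))
  # at the default band the same estimate is called
  expect_identical(copyCalls(callCopyNumbers(rel, m))["P_E8a", "copies"], 1L)
  # universal probe drifting just past the 3/4 midpoint hits the margin
  # guard instead of miscalling three copies
  rel2 <- setNames(rep(1, length(ids)), ids)
  rel2["U_E13"] <- 3.45 / 4
  expect_true(is.na(copyCalls(callCopyNumbers(rel2, m))["U_E13", "copies"]))
  # out-of-range estimates are never called
  rel2["U_E13"] <- 1.6   # 6.4 copies
  expect_true(is.na(copyCalls(callCopyNumbers(rel2, m))["U_E13", "copies"]))
})

test_that("called copies are monotone in true copies at sigma = 0", {
  m <- pmsMap
  ids <- probeSites(m)$id
  for (probe in c("P_E8a", "U_E13")) {
    ref <- referenceCopies(m)[probe]
    calls <- vapply(0:4, function(k) {
      rel <- setNames(rep(1, length(ids)), ids)
      rel[probe] <- k / ref
      copyCalls(callCopyNumbers(rel, m))[probe, "copies"]
    }, integer(1))
    expect_identical(calls, 0:4)
  }
})

test_that("the 2:2 criterion qualifies and disqualifies correctly", {
  m <- pmsMap
  panel <- noiseFreePanel(m)
  qc <- function(archetype) {
    rel <- archetypeRel(archetype, m, panel)
    qcReference(callCopyNumbers(rel, m), m)
  }
  expect_identical(qc("NORMAL")$status, "qualified")

  # one hybrid gene allele (pseudogene origin E14-E15) without reciprocal:
  # 1:3 at exon 14 discriminating sites
  e14 <- min(locusSites(m)$rank[locusSites(m)$exon_label == "E14"])
  g <- DiploidGenotype(
    list(paralogMLPA:::.hybridHap(m, "gene_locus", e14),
         paralogMLPA:::.pureHap(m, "gene_locus")),
    list(paralogMLPA:::.pureHap(m, "pseudogene_locus"),
         paralogMLPA:::.pureHap(m, "pseudogene_locus")))
  rel <- normalizeSignals(simulateProbeSignals(g, NoiseModel(0), m), panel, m)
  v <- qcReference(callCopyNumbers(rel, m), m)
  expect_identical(v$status, "disqualified")
  expect_setequal(v$offendingSites, c("P_E14a", "P_E14b", "PP_E14",
                                      "P_E15a", "P_E15b", "P_E15c", "PP_E15"))

  # the masked configuration passes the dosage criterion: documented blind spot
  expect_identical(qc("TR13_MASKED")$status, "qualified")

  # NO_CALL at a discriminating site gives a distinct indeterminate verdict
  rel <- archetypeRel("NORMAL", m, panel)
  rel["PP_E13"] <- 0.62
  v <- qcReference(callCopyNumbers(rel, m, band = 0.1), m)
  expect_identical(v$status, "indeterminate")
  expect_identical(v$noCallSites, "PP_E13")
})

test_that("panel construction drops unqualified candidates and reports shortfalls", {
  m <- pmsMap
  # all-normal candidates: everyone qualifies
  cand0 <- makeReferenceCandidates(5, PopulationModel(pHybridCarrier = 0), m,
                                   NoiseModel(sigma = 0))
  panel <- buildPanel(cand0$signals, m)
  expect_identical(length(panelMembers(panel)), 5L)

  # below the minimum size
  expect_error(buildPanel(cand0$signals[, 1:4], m), "4",
               class = "panel_construction_error")

  # a candidate cohort where about two thirds carry unbalancing hybrids:
  # the panel is drawn from the truly qualified candidates only
  set.seed(21)
  cand <- makeReferenceCandidates(24, PopulationModel(pHybridCarrier = 2/3), m,
                                  NoiseModel(0.05))
  panel <- buildPanel(cand$signals, m)
  expect_identical(length(panelMembers(panel)), 5L)
  truthOf <- setNames(cand$is_2_2, colnames(cand$signals))
  expect_true(all(truthOf[panelMembers(panel)]))
  # roughly one third of 24 candidates qualify
  verdicts <- attr(panel, "verdicts")
  expect_gt(sum(verdicts == "qualified"), 3)
  expect_lt(sum(verdicts == "qualified"), 14)
})

test_that("copy calls at sigma 0.05 with a qualified panel are calibrated", {
  m <- pmsMap
  set.seed(31)
  panel <- qualifiedPanel(m)
  gs <- samplePopulationGenotypes(1000, PopulationModel(), m)
  nm <- NoiseModel(0.05)
  stats <- vapply(gs, function(g) {
    truth <- expectedCopyVector(g, m)
    cc <- copyCalls(callCopyNumbers(
      normalizeSignals(simulateProbeSignals(g, nm, m), panel, m), m))
    called <- !is.na(cc$copies)
    c(correct = sum(cc$copies[called] == truth[cc$id][called]),
      called = sum(called), total = length(called))
  }, numeric(3))
  accuracy <- sum(stats["correct", ]) / sum(stats["called", ])
  expect_gte(accuracy, 0.99)
  # abstention stays rare
  expect_lt(1 - sum(stats["called", ]) / sum(stats["total", ]), 0.05)
})

test_that("signal tables round-trip through TSV", {
  m <- pmsMap
  set.seed(4)
  cand <- makeReferenceCandidates(3, PopulationModel(), m, NoiseModel(0.05))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSignalTSV(cand$signals, path)
  back <- readSignalTSV(path)
  expect_equal(back, cand$signals, tolerance = 1e-6)
})
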