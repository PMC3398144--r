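test_that("the intron-10 readout maps to the published breakpoint region", {
  m <- pmsMap
  g <- makeCaseGenotype("TR13", m)
  ro <- simulatePsvReadout(geneHaplotypes(g)[[1]], c(11, 13), m)
  bc <- mapBreakpoint(ro)
  expect_identical(bc@anchorUp, "c.1145-942")
  expect_identical(bc@anchorDown, "c.1145-790")
  expect_identical(regionLength(bc), 153L)
  expect_identical(nrow(interiorPsvs(bc)), 3L)
  expect_identical(interiorPsvs(bc)$origin, c("pseudogene", "gene", "gene"))
  expect_identical(mechanism(bc), "crossover")
})

test_that("breakpoint anchors are invariant to non-informative positions", {
  m <- pmsMap
  g <- makeCaseGenotype("TR13", m)
  ro <- simulatePsvReadout(geneHaplotypes(g)[[1]], c(11, 13), m)
  padded <- rbind(ro,
                  data.frame(id = c("X1", "X2"),
                             position = c("c.1145-1800", "c.1145-300"),
                             origin = c("gene", "pseudogene"),
                             observed_allele = c("A", "A")))
  bc <- mapBreakpoint(padded)
  expect_identical(bc@anchorUp, "c.1145-942")
  expect_identical(bc@anchorDown, "c.1145-790")
  expect_identical(regionLength(bc), 153L)
})

test_that("anchor selection equals a brute-force scan on random readouts", {
  # brute force: try every ordered position pair (p, q) and test the anchor
  # definition directly on the readout
  bruteAnchors <- function(ro) {
    n <- nrow(ro)
    a <- ro$origin[1]; b <- ro$origin[n]
    up <- NA_integer_; down <- NA_integer_
    for (p in seq_len(n)) if (all(ro$origin[1:p] == a)) up <- p
    for (q in rev(seq_len(n))) if (all(ro$origin[q:n] == b)) down <- q
    c(up = up, down = down)
  }
  set.seed(17)
  for (rep in 1:200) {
    n <- sample(2:20, 1)
    ro <- data.frame(position = sprintf("c.1145-%d", sort(sample(1:3000, n),
                                                          decreasing = TRUE)),
                     origin = sample(c("gene", "pseudogene"), n, replace = TRUE))
    if (length(unique(ro$origin)) == 1L) {
      expect_identical(mechanism(mapBreakpoint(ro)), "none")
      next
    }
    bc <- mapBreakpoint(ro)
    ba <- bruteAnchors(ro)
    expect_identical(bc@anchorUp, ro$position[ba["up"]])
    expect_identical(bc@anchorDown, ro$position[ba["down"]])
    expect_identical(mechanism(bc),
                     if (ro$origin[1] != ro$origin[n]) "crossover"
                     else "conversion_tract")
  }
})

test_that("conversion tracts and uniform readouts classify correctly", {
  m <- pmsMap
  conv <- Haplotype("gene_locus",
                    data.frame(start = 1L, end = 34L, origin = "gene"),
                    conversion = TRUE,
                    fineMap = c(PSV_E11_1730 = "pseudogene",
                                PSV_E11_1732 = "pseudogene"))
  bc <- mapBreakpoint(simulatePsvReadout(conv, c(12, 16), m))
  expect_identical(mechanism(bc), "conversion_tract")
  expect_true(all(interiorPsvs(bc)$origin == "pseudogene"))

  pure <- paralogMLPA:::.pureHap(m, "gene_locus")
  bc0 <- mapBreakpoint(simulatePsvReadout(pure, c(11, 13), m))
  expect_identical(mechanism(bc0), "none")
  expect_true(is.na(bc0@anchorUp) && is.na(bc0@anchorDown))
})

test_that("readout TSVs resolve origins from observed alleles", {
  m <- pmsMap
  g <- makeCaseGenotype("TR13", m)
  ro <- simulatePsvReadout(geneHaplotypes(g)[[1]], c(11, 13), m)
  pv <- psvCatalog(m)
  tsv <- data.frame(position = ro$position,
                    gene_allele = pv$gene_allele[match(ro$id, pv$id)],
                    pseudogene_allele = pv$pseudogene_allele[match(ro$id, pv$id)],
                    observed_allele = ro$observed_allele)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tsv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readPsvReadoutTSV(path)
  expect_identical(back$origin, ro$origin)
  expect_identical(regionLength(mapBreakpoint(back)), 153L)
})

test_that("the in-silico ASP assay detects the crossover haplotype only", {
  m <- pmsMap
  assay <- aspAssays(m)[[1]]
  res <- insilicoASP(makeCaseGenotype("TR13", m), assay, m)
  expect_identical(res$present, c(TRUE, TRUE))
  expect_identical(res$length_bp, c(239L, 696L))

  res <- insilicoASP(makeCaseGenotype("NORMAL", m), assay, m)
  expect_identical(res$present, c(FALSE, TRUE))

  # resolves the MLPA blind spot: masked genotype still amplifies
  res <- insilicoASP(makeCaseGenotype("TR13_MASKED", m), assay, m)
  expect_true(res$present[1])

  # whole-gene deletion: no allele-specific product, control from the
  # remaining haplotypes
  res <- insilicoASP(makeCaseGenotype("CH8", m), assay, m)
  expect_identical(res$present, c(FALSE, TRUE))

  out <- new("ASPAssay", id = "out", forwardPos = "c.90000",
             forwardOrigin = "gene", reversePos = "c.95000",
             reverseOrigin = "pseudogene", productLengthBp = 100L,
             controlLengthBp = 100L)
  expect_error(insilicoASP(makeCaseGenotype("NORMAL", m), out, m),
               class = "range_error")
})

test_that("no background genotype ever amplifies the allele-specific product", {
  m <- pmsMap
  assay <- aspAssays(m)[[1]]
  set.seed(12)
  gs <- samplePopulationGenotypes(10000, PopulationModel(), m)
  pos <- vapply(gs, function(g) insilicoASP(g, assay, m)$present[1], NA)
  expect_identical(sum(pos), 0L)
})

test_that("array tracks bound the deletion from both sides", {
  ch8 <- data.frame(pos = c(5970140, 5970432, 6095502, 6097302),
                    state = c("retained", "deleted", "deleted", "retained"))
  b <- boundDeletion(ch8)
  expect_identical(b$min_size_bp, 125070)
  expect_identical(b$max_size_bp, 127162)
  expect_identical(b$distal_interval, c(5970140, 5970432))
  expect_identical(b$proximal_interval, c(6095502, 6097302))
  expect_false(b$one_sided)

  toy <- data.frame(pos = c(0, 100, 200),
                    state = c("retained", "deleted", "retained"))
  bt <- boundDeletion(toy)
  expect_identical(bt$distal_interval, c(0, 100))
  expect_identical(bt$proximal_interval, c(100, 200))

  expect_identical(length(boundDeletion(
    data.frame(pos = 1:3, state = rep("retained", 3)))), 0L)

  edge <- boundDeletion(data.frame(pos = c(0, 100, 200),
                                   state = c("deleted", "deleted", "retained")))
  expect_true(edge$one_sided)
})

test_that("deletion bounds are ordered and translation invariant", {
  set.seed(23)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    run <- sort(sample(2:(n - 1), 2))
    st <- rep("retained", n); st[run[1]:run[2]] <- "deleted"
    pos <- cumsum(sample(1:1000, n))
    b1 <- boundDeletion(data.frame(pos = pos, state = st))
    expect_lte(b1$min_size_bp, b1$max_size_bp)
    b2 <- boundDeletion(data.frame(pos = pos + 5e6, state = st))
    expect_identical(b1$min_size_bp, b2$min_size_bp)
    expect_identical(b1$max_size_bp, b2$max_size_bp)
  }
})

test_that("the recombination clock returns the reciprocal waiting time", {
  expect_equal(expectedGenerations(0.7, 1.1), 100 / 0.77, tolerance = 1e-12)
  expect_equal(round(expectedGenerations(0.7, 1.1), -1), 130)
  expect_equal(expectedGenerations(1, 1), 100)
  # halving the interval doubles the waiting time
  expect_equal(expectedGenerations(0.35, 1.1), 2 * expectedGenerations(0.7, 1.1))
  expect_error(expectedGenerations(0, 1.1), class = "parameter_error")
  expect_error(expectedGenerations(0.7, -1), class = "parameter_error")
  expect_error(expectedGenerations(100, 1), class = "parameter_error")
})
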