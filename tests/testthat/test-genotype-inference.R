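test_that("gene-locus haplotypes classify by tract extent and deletions", {
  m <- pmsMap
  g <- makeCaseGenotype("TR13", m)
  expect_identical(classifyHaplotype(geneHaplotypes(g)[[1]], m),
                   "deleterious_hybrid")
  # exon-15-only pseudogene origin is nondeleterious (3'UTR duplication)
  expect_identical(classifyHaplotype(geneHaplotypes(g)[[2]], m),
                   "nondeleterious_hybrid")
  e13 <- min(locusSites(m)$rank[locusSites(m)$exon_label == "E13"])
  expect_identical(classifyHaplotype(paralogMLPA:::.hybridHap(m, "gene_locus", e13), m),
                   "nondeleterious_hybrid")
  expect_identical(classifyHaplotype(paralogMLPA:::.pureHap(m, "gene_locus"), m),
                   "normal")
  ch8 <- makeCaseGenotype("CH8", m)
  expect_identical(classifyHaplotype(geneHaplotypes(ch8)[[1]], m),
                   "whole_gene_deletion")
  ch11 <- makeCaseGenotype("CH11", m)
  expect_identical(classifyHaplotype(geneHaplotypes(ch11)[[1]], m),
                   "exon_deletion")
  # pseudogene-origin starting 5' of exon 10 loses the exon-10 block
  e9 <- min(locusSites(m)$rank[locusSites(m)$exon_label == "E9"])
  expect_identical(classifyHaplotype(paralogMLPA:::.hybridHap(m, "gene_locus", e9), m),
                   "deleterious_hybrid")
  # conversion tract planting a frameshift PSV on the gene background
  conv <- Haplotype("gene_locus",
                    data.frame(start = 1L, end = 34L, origin = "gene"),
                    conversion = TRUE,
                    fineMap = c(PSV_E11_1730 = "pseudogene"))
  expect_identical(classifyHaplotype(conv, m), "deleterious_hybrid")
  expect_error(classifyHaplotype(paralogMLPA:::.pureHap(m, "pseudogene_locus"), m),
               "gene-locus")
})

test_that("the intron-10 crossover profile deduces to the published genotype", {
  m <- pmsMap
  rel <- archetypeRel("TR13", m)
  ss <- enumerateGenotypes(callCopyNumbers(rel, m, sampleId = "TR13"), m)
  expect_identical(classification(ss), "deleterious")
  minimal <- solutionEvents(ss) == min(solutionEvents(ss))
  shared <- paralogMLPA:::.sharedStart(m)
  # every minimal solution contains a gene-locus haplotype with pseudogene
  # origin from the start of exon 11
  for (sol in solutions(ss)[minimal]) {
    hit <- vapply(geneHaplotypes(sol), function(h) {
      seg <- h@segments
      nrow(seg) == 2L && seg$origin[2] == "pseudogene" && seg$start[2] == shared
    }, NA)
    expect_true(any(hit))
  }
})

test_that("the whole-gene-deletion profile deduces to deletion plus two hybrids", {
  m <- pmsMap
  rel <- archetypeRel("CH8", m)
  ss <- enumerateGenotypes(callCopyNumbers(rel, m, sampleId = "CH8"), m)
  expect_identical(classification(ss), "deleterious")
  minimal <- which(solutionEvents(ss) == min(solutionEvents(ss)))
  expect_identical(length(minimal), 1L)
  sol <- solutions(ss)[[minimal]]
  cls <- vapply(geneHaplotypes(sol), classifyHaplotype, "", m = m)
  expect_setequal(cls, c("whole_gene_deletion", "normal"))
  e13 <- min(locusSites(m)$rank[locusSites(m)$exon_label == "E13"])
  for (h in pseudoHaplotypes(sol)) {
    expect_identical(nrow(h@segments), 2L)
    expect_identical(h@segments$origin[2], "gene")
    expect_identical(h@segments$start[2], e13)
  }
})

test_that("a balanced 2:2 profile is ambiguous: normal or masked hybrid pair", {
  m <- pmsMap
  rel <- archetypeRel("NORMAL", m)
  ss <- enumerateGenotypes(callCopyNumbers(rel, m, sampleId = "N"), m)
  expect_identical(classification(ss), "ambiguous")
  encs <- vapply(solutions(ss), encodeGenotype, "")
  expect_true(encodeGenotype(makeCaseGenotype("NORMAL", m)) %in% encs)
  # the deleterious hybrid with its reciprocal (origins switching at the
  # start of exon 11 on both loci) is among the solutions
  shared <- paralogMLPA:::.sharedStart(m)
  masked <- DiploidGenotype(
    list(paralogMLPA:::.hybridHap(m, "gene_locus", shared),
         paralogMLPA:::.pureHap(m, "gene_locus")),
    list(paralogMLPA:::.hybridHap(m, "pseudogene_locus", shared),
         paralogMLPA:::.pureHap(m, "pseudogene_locus")))
  expect_true(encodeGenotype(masked) %in% encs)
})

test_that("enumeration equals a brute-force generate-and-filter oracle", {
  m <- tinyMap()
  gh <- bruteStates(m, "gene_locus")
  ph <- bruteStates(m, "pseudogene_locus")
  set.seed(99)
  for (rep in 1:200) {
    g <- DiploidGenotype(
      list(gh[[sample(length(gh), 1)]], gh[[sample(length(gh), 1)]]),
      list(ph[[sample(length(ph), 1)]], ph[[sample(length(ph), 1)]]))
    v <- expectedCopyVector(g, m)[locusSites(m)$id]
    v[runif(length(v)) < 0.2] <- NA    # NO_CALL wildcards
    prof <- makeProfile(v, m)
    bf <- bruteForceEnumerate(prof, m)
    ss <- enumerateGenotypes(prof, m, maxSolutions = 100000L)
    expect_identical(sort(vapply(solutions(ss), encodeGenotype, "")),
                     sort(bf$enc))
    expect_identical(sort(as.integer(solutionEvents(ss))),
                     sort(as.integer(bf$events)))
  }
})

test_that("every returned solution reproduces the called profile", {
  m <- pmsMap
  for (a in c("TR13", "CH8", "CH11")) {
    rel <- archetypeRel(a, m)
    prof <- callCopyNumbers(rel, m, sampleId = a)
    cc <- copyCalls(prof)
    called <- !is.na(cc$copies)
    ss <- enumerateGenotypes(prof, m)
    for (sol in solutions(ss)) {
      v <- expectedCopyVector(sol, m)
      expect_identical(unname(v[cc$id[called]]), cc$copies[called])
    }
  }
})

test_that("unsatisfiable profiles are reported uninterpretable", {
  m <- pmsMap
  v <- setNames(rep(2L, 34), locusSites(m)$id)
  v["U_E13"] <- 0L   # four specific copies but zero combined: impossible
  ss <- enumerateGenotypes(makeProfile(v, m), m)
  expect_identical(classification(ss), "uninterpretable")
  expect_identical(length(solutions(ss)), 0L)
})

test_that("sample interpretation flags aberrance and recommends follow-up", {
  m <- pmsMap
  panel <- noiseFreePanel(m)
  report <- function(a) interpretSample(
    callCopyNumbers(archetypeRel(a, m, panel), m, sampleId = a), m)

  r <- report("CH11")
  expect_true(r$aberrant)
  expect_identical(r$classification, "deleterious")
  ss <- r$solutionSet
  sol <- solutions(ss)[[which.min(solutionEvents(ss))]]
  expect_true("exon_deletion" %in%
                vapply(geneHaplotypes(sol), classifyHaplotype, "", m = m))

  r <- report("NORMAL")
  expect_false(r$aberrant)
  expect_identical(r$classification, "normal")

  # masked configuration: identical dosage, resolved only by the ASP check
  r <- report("TR13_MASKED")
  expect_false(r$aberrant)
  expect_identical(r$classification, "normal")
  expect_true(r$maskingPossible)
  expect_match(r$followUp, "allele-specific PCR")
})
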