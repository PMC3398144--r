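# Shared fixtures: the packaged locus, a tiny locus for brute-force
# enumeration checks, profile builders and genotype encodings.

pmsMap <- pms2LocusMap()

tinyMap <- function() {
  loadLocusMap(list(
    geometry = list(exon10_span_kb = 2.7, duplicon_inverted = TRUE,
                    interduplicon_distance_mb = 0.7),
    probe_sites = list(
      list(id = "tP_E10", exon = "E10", specificity = "gene", ligation = "c.1000_1001"),
      list(id = "tP_E11", exon = "E11", specificity = "gene", ligation = "c.1200_1201"),
      list(id = "tPP_E11", exon = "E11", specificity = "pseudogene", ligation = "c.1300_1301"),
      list(id = "tU_E12", exon = "E12", specificity = "universal", ligation = "c.1450_1451"),
      list(id = "tP_E13", exon = "E13", specificity = "gene", ligation = "c.1600_1601"),
      list(id = "tPP_E13", exon = "E13", specificity = "pseudogene", ligation = "c.1650_1651"),
      list(id = "tU_E15", exon = "E15", specificity = "universal", ligation = "c.1900_1901"),
      list(id = "tREF1", exon = "REF", specificity = "reference"),
      list(id = "tREF2", exon = "REF", specificity = "reference")),
    psv_catalog = list(
      list(id = "tPSV1", position = "c.1250A>G", gene_allele = "A",
           pseudogene_allele = "G", kind = "substitution", consequence = "synonymous"),
      list(id = "tPSV2", position = "c.1620C>T", gene_allele = "C",
           pseudogene_allele = "T", kind = "substitution", consequence = "synonymous"))))
}

# CopyNumberProfile straight from a (possibly partial, NA = NO_CALL)
# named copy vector; unspecified probes default to the reference state
makeProfile <- function(copies, m, id = "t") {
  ps <- probeSites(m)
  ref <- referenceCopies(m)
  full <- setNames(ifelse(ps$specificity == "universal", 4L, 2L), ps$id)
  full[names(copies)] <- copies
  new("CopyNumberProfile", sampleId = id,
      calls = data.frame(id = names(full),
                         relative_signal = ifelse(is.na(full), 1,
                                                  full / ref[names(full)]),
                         copies = unname(full),
                         ref_copies = unname(ref[names(full)]),
                         row.names = names(full)))
}

encodeHap <- function(h) paste0(substr(h@locus, 1, 1), "[",
  paste(h@segments$start, h@segments$end, substr(h@segments$origin, 1, 1),
        sep = ":", collapse = ","), "]",
  if (nrow(h@deletions)) paste0("del", paste(h@deletions$start, h@deletions$end,
                                             sep = "-", collapse = ",")) else "")

encodeGenotype <- function(g) paste(
  paste(sort(vapply(geneHaplotypes(g), encodeHap, "")), collapse = "|"),
  paste(sort(vapply(pseudoHaplotypes(g), encodeHap, "")), collapse = "|"),
  sep = "||")

# every bounded single-event haplotype state as a Haplotype object,
# generated independently of the enumeration engine's state tables
bruteStates <- function(m, locus) {
  ax <- paralogMLPA:::.locusAxis(m, locus)
  ps <- locusSites(m)
  hom <- ps$rank[!ps$exon_label %in% paste0("E", 1:8)]
  bpFrom <- if (locus == "gene_locus") max(ax[1], min(hom)) else ax[1]
  haps <- list(paralogMLPA:::.pureHap(m, locus))
  for (b in bpFrom:ax[2]) haps <- c(haps, paralogMLPA:::.hybridHap(m, locus, b))
  if (locus == "gene_locus") {
    det <- sort(ps$rank[ps$specificity %in% c("gene", "universal")])
    for (i in det) for (j in det[det >= i]) {
      h <- paralogMLPA:::.pureHap(m, locus)
      h@deletions <- data.frame(start = i, end = j)
      haps <- c(haps, h)
    }
  }
  haps
}

# generator-and-filter oracle: quadruple loop over haplotype states, copy
# vectors summed per haplotype, filtered against the called sites
bruteForceEnumerate <- function(profile, m) {
  ps <- locusSites(m)
  cl <- copyCalls(profile)[match(ps$id, copyCalls(profile)$id), ]
  called <- !is.na(cl$copies)
  gh <- bruteStates(m, "gene_locus"); ph <- bruteStates(m, "pseudogene_locus")
  gC <- t(vapply(gh, paralogMLPA:::.hapContrib, numeric(nrow(ps)), m = m))
  pC <- t(vapply(ph, paralogMLPA:::.hapContrib, numeric(nrow(ps)), m = m))
  isEvent <- function(h) nrow(h@segments) > 1L || nrow(h@deletions) > 0L ||
    h@segments$origin[1] != if (h@locus == "gene_locus") "gene" else "pseudogene"
  out <- character(0); ev <- integer(0)
  for (i in seq_along(gh)) for (j in i:length(gh))
    for (k in seq_along(ph)) for (l in k:length(ph)) {
      v <- gC[i, ] + gC[j, ] + pC[k, ] + pC[l, ]
      if (all(v[called] == cl$copies[called])) {
        g <- DiploidGenotype(list(gh[[i]], gh[[j]]), list(ph[[k]], ph[[l]]))
        out <- c(out, encodeGenotype(g))
        ev <- c(ev, sum(vapply(list(gh[[i]], gh[[j]], ph[[k]], ph[[l]]),
                               isEvent, NA)))
      }
    }
  list(enc = out, events = ev)
}

# qualified reference panel built from noise-free normal candidates
noiseFreePanel <- function(m, n = 6L) {
  cand <- makeReferenceCandidates(n, PopulationModel(pHybridCarrier = 0), m,
                                  NoiseModel(sigma = 0))
  buildPanel(cand$signals, m)
}

# candidate acquisition as in practice: keep evaluating 24-sample candidate
# batches (under the current RNG stream) until five qualify
qualifiedPanel <- function(m, sigma = 0.05, maxBatches = 10L) {
  for (b in seq_len(maxBatches)) {
    cand <- makeReferenceCandidates(24, PopulationModel(), m, NoiseModel(sigma))
    panel <- tryCatch(buildPanel(cand$signals, m),
                      error = function(e) NULL)
    if (!is.null(panel)) return(panel)
  }
  stop("no qualifying candidate batch in ", maxBatches, " draws")
}

# relative signals of an archetype sample against a noise-free panel
archetypeRel <- function(archetype, m, panel = noiseFreePanel(m), sigma = 0,
                         seed = NA_integer_) {
  s <- simulateProbeSignals(makeCaseGenotype(archetype, m),
                            NoiseModel(sigma = sigma, seed = seed), m)
  normalizeSignals(s, panel, m)
}
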