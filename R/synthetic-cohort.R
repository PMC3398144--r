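#' @title Synthetic cohort generation
#' @description Generators that emulate everything the original study drew
#'   from patients and repository DNAs: diploid genotypes (population
#'   backgrounds and the three patient archetypes), noisy MLPA probe
#'   signals, PSV origin readouts of hybrid amplicons, and labelled
#'   reference-candidate panels.
#' @name synthetic_cohort
NULL

# evaluate expr under a temporary seed, restoring the session RNG state
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

.pureHap <- function(m, locus, label = "") {
  ax <- .locusAxis(m, locus)
  origin <- if (locus == "gene_locus") "gene" else "pseudogene"
  Haplotype(locus, data.frame(start = ax[1], end = ax[2], origin = origin),
            label = label)
}

# host origin 5' -> paralog origin from rank `from` on
.hybridHap <- function(m, locus, from, label = "", fineAnchors = c(NA, NA),
                       fineMap = character(0)) {
  ax <- .locusAxis(m, locus)
  host <- if (locus == "gene_locus") "gene" else "pseudogene"
  par <- setdiff(c("gene", "pseudogene"), host)
  seg <- if (from <= ax[1]) {
    data.frame(start = ax[1], end = ax[2], origin = par)
  } else {
    data.frame(start = c(ax[1], from), end = c(from - 1L, ax[2]),
               origin = c(host, par))
  }
  Haplotype(locus, seg, fineAnchors = as.character(fineAnchors),
            fineMap = fineMap, label = label)
}

# the intron-10 crossover hybrid of the index patient: gene origin through
# c.1145-942, pseudogene origin from c.1145-790 on, with the published
# interior PSV pattern left by double-Holliday-junction resolution
.ivs10CrossoverHap <- function(m) {
  .hybridHap(m, "gene_locus", from = .sharedStart(m),
             label = "deleterious IVS10 crossover hybrid",
             fineAnchors = c("c.1145-942", "c.1145-790"),
             fineMap = c(PSV_IVS10_921 = "pseudogene",
                         PSV_IVS10_886 = "gene",
                         PSV_IVS10_880 = "gene"))
}

#' Construct a patient-archetype genotype
#'
#' The three aberrant archetypes reproduce the study's patients:
#' \describe{
#'   \item{CH8}{whole-gene-locus deletion on one chromosome, a normal gene
#'     allele, and two hybrid pseudogene alleles with gene-origin sequence
#'     in exons 13-15.}
#'   \item{CH11}{heterozygous genomic deletion of exon 8.}
#'   \item{TR13}{a deleterious hybrid gene allele with pseudogene origin
#'     from the start of exon 11 (intron-10 crossover), a nondeleterious
#'     hybrid gene allele with exon-15-only pseudogene origin, one pure
#'     pseudogene allele and one hybrid pseudogene allele with gene origin
#'     in exons 13-15.}
#'   \item{TR13_MASKED}{the deleterious intron-10 hybrid together with its
#'     reciprocal hybrid pseudogene allele: the copy vector is identical to
#'     NORMAL at every probe (the MLPA blind spot).}
#' }
#'
#' @param archetype one of \code{"NORMAL"}, \code{"CH8"}, \code{"CH11"},
#'   \code{"TR13"}, \code{"TR13_MASKED"}.
#' @param m a \code{\linkS4class{LocusMap}}.
#' @return a \code{\linkS4class{DiploidGenotype}}.
#' @examples
#' m <- pms2LocusMap()
#' expectedCopyVector(makeCaseGenotype("TR13", m), m)
#' @export
makeCaseGenotype <- function(archetype, m) {
  stopifnot(is(m, "LocusMap"))
  e13 <- min(.ranksOf(m, "E13"))
  e15 <- min(.ranksOf(m, "E15"))
  ax <- .locusAxis(m, "gene_locus")
  pureG <- function(lab = "normal gene allele") .pureHap(m, "gene_locus", lab)
  pureP <- function(lab = "pseudogene allele") .pureHap(m, "pseudogene_locus", lab)
  hybP13 <- function(lab) .hybridHap(m, "pseudogene_locus", e13, lab)
  switch(archetype,
    NORMAL = DiploidGenotype(list(pureG(), pureG()), list(pureP(), pureP()),
                             label = "NORMAL"),
    CH8 = DiploidGenotype(
      list(Haplotype("gene_locus",
                     data.frame(start = ax[1], end = ax[2], origin = "gene"),
                     deletions = data.frame(start = ax[1], end = ax[2]),
                     label = "whole-gene deletion"),
           pureG()),
      list(hybP13("hybrid pseudogene, gene origin E13-E15"),
           hybP13("hybrid pseudogene, gene origin E13-E15")),
      label = "CH8"),
    CH11 = {
      e8 <- .ranksOf(m, "E8")
      DiploidGenotype(
        list(Haplotype("gene_locus",
                       data.frame(start = ax[1], end = ax[2], origin = "gene"),
                       deletions = data.frame(start = min(e8), end = max(e8)),
                       label = "exon-8 deletion"),
             pureG()),
        list(pureP(), pureP()), label = "CH11")
    },
    TR13 = DiploidGenotype(
      list(.ivs10CrossoverHap(m),
           .hybridHap(m, "gene_locus", e15,
                      label = "nondeleterious hybrid, E15-only pseudogene origin")),
      list(pureP(), hybP13("hybrid pseudogene, gene origin E13-E15")),
      label = "TR13"),
    TR13_MASKED = DiploidGenotype(
      list(.ivs10CrossoverHap(m), pureG()),
      list(pureP(),
           .hybridHap(m, "pseudogene_locus", .sharedStart(m),
                      label = "reciprocal hybrid pseudogene allele",
                      fineAnchors = c("c.1145-942", "c.1145-790"))),
      label = "TR13_MASKED"),
    stop("unknown archetype: '", archetype, "'", call. = FALSE)
  )
}

#' Draw a nondeleterious background genotype from the population model
#'
#' Each of the four haplotypes is independently a hybrid with probability
#' \code{q = 1 - (1 - pHybridCarrier)^(1/4)}, so the fraction of
#' individuals carrying at least one hybrid allele converges to
#' \code{pHybridCarrier}. Hybrid tract starts are restricted to the allowed
#' nondeleterious boundaries (3' of exon 12); among gene-locus hybrids the
#' exon-14-covering classes receive total allele fraction
#' \code{pN775SAllele}, the remainder falls on the exon-15-only class.
#' No deletions are drawn: every background genotype has four copies at
#' every universal site.
#'
#' @param pm a \code{\linkS4class{PopulationModel}}.
#' @param m a \code{\linkS4class{LocusMap}}.
#' @return a \code{\linkS4class{DiploidGenotype}} containing only
#'   nondeleterious configurations.
#' @export
samplePopulationGenotype <- function(pm, m) {
  samplePopulationGenotypes(1L, pm, m)[[1]]
}

#' @describeIn samplePopulationGenotype draw \code{n} background genotypes
#'   at once (the haplotype pool is precomputed, so large draws are cheap).
#' @param n number of genotypes to draw.
#' @return for the batch version, a list of \code{n} genotypes.
#' @export
samplePopulationGenotypes <- function(n, pm, m) {
  stopifnot(is(pm, "PopulationModel"), is(m, "LocusMap"), n >= 0)
  q <- 1 - (1 - pm@pHybridCarrier)^(1 / 4)
  bks <- pm@allowedBreakpoints
  cover14 <- intersect(bks, c("IVS12", "E13", "E14"))
  w14 <- if (q > 0 && length(cover14)) min(pm@pN775SAllele, q) / q else 0
  if (!"E15" %in% bks) w14 <- if (length(cover14)) 1 else 0
  # every population haplotype is one of a small immutable pool
  pool <- lapply(c(gene_locus = "gene_locus",
                   pseudogene_locus = "pseudogene_locus"), function(locus) {
    hy <- lapply(stats::setNames(nm = bks), function(lab)
      .hybridHap(m, locus, min(.ranksOf(m, lab)),
                 label = paste0("nondeleterious hybrid from ", lab)))
    c(list(pure = .pureHap(m, locus)), hy)
  })
  template <- DiploidGenotype(
    list(pool$gene_locus$pure, pool$gene_locus$pure),
    list(pool$pseudogene_locus$pure, pool$pseudogene_locus$pure),
    label = "population")
  drawFrom <- function(locus) {
    if (stats::runif(1) >= q) return(pool[[locus]]$pure)
    lab <- if (length(cover14) && stats::runif(1) < w14)
      sample(cover14, 1L) else "E15"
    pool[[locus]][[lab]]
  }
  lapply(seq_len(n), function(i) {
    g <- template
    g@geneHaplotypes <- list(drawFrom("gene_locus"), drawFrom("gene_locus"))
    g@pseudoHaplotypes <- list(drawFrom("pseudogene_locus"),
                               drawFrom("pseudogene_locus"))
    g
  })
}

#' Simulate raw MLPA probe signals for one genotype
#'
#' Forward model of the assay's signal semantics: the raw signal of a probe
#' is \code{100 * (true copies / reference copies) * exp(N(0, sigma))},
#' where reference copies are 2 for paralog-specific and reference probes
#' and 4 for universal probes. With \code{sigma = 0} and a matched panel
#' the normalised relative signal of an unaltered probe is exactly 1.
#'
#' @param g a \code{\linkS4class{DiploidGenotype}}.
#' @param nm a \code{\linkS4class{NoiseModel}}.
#' @param m a \code{\linkS4class{LocusMap}}.
#' @return named numeric vector of raw signals (arbitrary units), one entry
#'   per probe site.
#' @export
simulateProbeSignals <- function(g, nm, m) {
  stopifnot(is(nm, "NoiseModel"))
  copies <- expectedCopyVector(g, m)
  ref <- referenceCopies(m)[names(copies)]
  base <- 100 * copies / ref
  .withSeed(nm@seed, base * exp(stats::rnorm(length(base), 0, nm@sigma)))
}

#' Generate labelled reference-candidate samples
#'
#' Draws \code{n} genotypes from the population model, simulates their raw
#' probe signals, and labels each candidate with the ground truth of the
#' reference-qualification criterion: \code{TRUE} iff the genotype carries
#' exactly two gene-origin and two pseudogene-origin copies at every
#' paralog-discriminating probe site in the exon 11-15 region.
#'
#' @param n number of candidates (>= 1).
#' @param pm a \code{\linkS4class{PopulationModel}}.
#' @param m a \code{\linkS4class{LocusMap}}.
#' @param nm a \code{\linkS4class{NoiseModel}}.
#' @return list with \code{signals} (matrix probes x candidates),
#'   \code{is_2_2} (logical truth labels) and \code{genotypes}.
#' @export
makeReferenceCandidates <- function(n, pm, m, nm = NoiseModel()) {
  stopifnot(n >= 1)
  disc <- discriminatingSites(m)
  genotypes <- samplePopulationGenotypes(n, pm, m)
  is22 <- vapply(genotypes, function(g)
    all(expectedCopyVector(g, m)[disc] == 2L), logical(1))
  sig <- vapply(genotypes, simulateProbeSignals, nm = nm, m = m,
                FUN.VALUE = numeric(nrow(m@probeSites)))
  colnames(sig) <- sprintf("cand%02d", seq_len(n))
  list(signals = sig, is_2_2 = is22, genotypes = genotypes)
}

#' Paralog-discriminating probe sites of the exon 11-15 region
#'
#' @param m a \code{\linkS4class{LocusMap}}.
#' @return character vector of probe ids (gene- and pseudogene-specific
#'   sites in exons 11-15 and intron 12), the sites the 2:2
#'   reference-qualification criterion is evaluated on.
#' @export
discriminatingSites <- function(m) {
  ps <- m@probeSites
  ps$id[ps$specificity %in% c("gene", "pseudogene") &
          ps$exon_label %in% c("E11", "E12", "IVS12", "E13", "E14", "E15")]
}

# origin of a haplotype at an arbitrary transcript position (order key).
# Returns "gene", "pseudogene" or NA (no template / indeterminate).
.hapOriginAtKey <- function(h, m, key) {
  ps <- locusSites(m)              # rank order
  ax <- range(c(h@segments$start, h@segments$end))
  ori <- .hapOriginByRank(h, m)
  del <- .hapDeletedByRank(h, m)
  inAx <- ps$rank >= ax[1] & ps$rank <= ax[2]
  host <- if (h@locus == "gene_locus") "gene" else "pseudogene"
  upIdx <- which(inAx & ps$key <= key)
  dnIdx <- which(inAx & ps$key >= key)
  left <- if (length(upIdx)) {
    r <- ps$rank[max(upIdx)]
    if (del[r]) NA_character_ else ori[r]
  } else host
  right <- if (length(dnIdx)) {
    r <- ps$rank[min(dnIdx)]
    if (del[r]) NA_character_ else ori[r]
  } else host
  if (identical(left, right)) return(left)
  if (length(upIdx) && length(dnIdx)) {
    r1 <- ps$rank[max(upIdx)]; r2 <- ps$rank[min(dnIdx)]
    if (del[r1] && del[r2]) return(NA_character_)
  }
  fa <- h@fineAnchors
  if (!all(is.na(fa))) {
    kUp <- hgvsKey(fa[1], end = TRUE); kDn <- hgvsKey(fa[2])
    if (key <= kUp) return(left)
    if (key >= kDn) return(right)
    return(NA_character_)          # inside the breakpoint region
  }
  # no sub-probe localisation: attribute the gap to the upstream segment
  left
}

#' Simulate the PSV origin readout of one haplotype over a region
#'
#' Emulates sequencing a long-range amplicon from a single haplotype and
#' typing every paralog-discriminating site it contains: each PSV between
#' the ligation positions of the region's bounding probe ranks reports the
#' origin of the haplotype segment covering it. Sub-probe breakpoint
#' regions and conversion tracts use the haplotype's fine annotations, so
#' crossover haplotypes reproduce the interleaved interior pattern left by
#' Holliday-junction resolution.
#'
#' @param h a \code{\linkS4class{Haplotype}}.
#' @param region integer(2), rank interval (within the locus site axis).
#' @param m a \code{\linkS4class{LocusMap}}.
#' @return data.frame \code{id}, \code{position}, \code{origin},
#'   \code{observed_allele}, ordered 5' to 3'.
#' @examples
#' m <- pms2LocusMap()
#' g <- makeCaseGenotype("TR13", m)
#' simulatePsvReadout(geneHaplotypes(g)[[1]], c(11, 16), m)
#' @export
simulatePsvReadout <- function(h, region, m) {
  stopifnot(is(h, "Haplotype"), length(region) == 2L)
  n <- .nLocusSites(m)
  if (region[1] < 1L || region[2] > n || region[1] > region[2])
    stop(errorCondition(sprintf("region [%d, %d] outside the locus site axis (1..%d)",
                                region[1], region[2], n),
                        class = c("range_error", "error", "condition")))
  ax <- range(c(h@segments$start, h@segments$end))
  if (region[1] < ax[1] || region[2] > ax[2])
    stop(errorCondition("haplotype does not cover the requested region",
                        class = c("range_error", "error", "condition")))
  ps <- locusSites(m)
  kLo <- ps$key[ps$rank == region[1]]
  kHi <- ps$key[ps$rank == region[2]]
  pv <- m@psvCatalog
  pv <- pv[pv$key >= kLo & pv$key <= kHi, , drop = FALSE]
  origin <- vapply(seq_len(nrow(pv)), function(i) {
    id <- pv$id[i]
    if (id %in% names(h@fineMap)) h@fineMap[[id]]
    else .hapOriginAtKey(h, m, pv$key[i])
  }, character(1))
  data.frame(id = pv$id, position = pv$position, origin = origin,
             observed_allele = ifelse(origin == "gene", pv$gene_allele,
                                      pv$pseudogene_allele),
             row.names = NULL)
}
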