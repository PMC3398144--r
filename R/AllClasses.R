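#' @import methods
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))

# ---------------------------------------------------------------------------
# LocusMap
# ---------------------------------------------------------------------------

#' LocusMap: probe, PSV and duplicon geometry of a two-paralog locus
#'
#' A \code{LocusMap} encodes everything the dosage and breakpoint machinery
#' needs to know about a gene/pseudogene pair: the MLPA probe ligation sites
#' (with paralog specificity), the catalog of paralogous sequence variants
#' (PSVs), the exon table anchoring HGVS intronic offsets, and the duplicon
#' geometry (orientation, interduplicon distance, extent of the exon-10
#' block absent from the pseudogene).
#'
#' Probe sites carry a transcript-ordered integer \code{rank} computed once
#' at load time; all positional comparisons use ranks or the numeric HGVS
#' order key, never string comparison. Off-locus reference (control) probes
#' carry \code{rank = NA} and take no part in genotype arithmetic; they
#' anchor intra-sample signal scaling.
#'
#' @slot probeSites data.frame with columns \code{id}, \code{exon_label},
#'   \code{rank}, \code{specificity} (\code{gene}, \code{pseudogene},
#'   \code{universal} or \code{reference}), \code{ligation_pos} (HGVS) and
#'   \code{key} (numeric order key; NA for reference probes).
#' @slot psvCatalog data.frame with columns \code{id}, \code{position},
#'   \code{gene_allele}, \code{pseudogene_allele}, \code{kind},
#'   \code{consequence}, \code{key}.
#' @slot exonTable data.frame with columns \code{exon}, \code{cds_start},
#'   \code{cds_end} (coding coordinates of each exon).
#' @slot exon10SpanKb numeric, size of the block absent from the pseudogene.
#' @slot dupliconInverted logical, paralogs lie on opposite strands.
#' @slot interdupliconDistanceMb numeric, distance between the duplicons.
#' @slot assays list of packaged \code{ASPAssay} objects (may be empty).
#'
#' @seealso \code{\link{loadLocusMap}}, \code{\link{pms2LocusMap}}
#' @export
setClass("LocusMap", representation(
  probeSites = "data.frame",
  psvCatalog = "data.frame",
  exonTable = "data.frame",
  exon10SpanKb = "numeric",
  dupliconInverted = "logical",
  interdupliconDistanceMb = "numeric",
  assays = "list"
))

setValidity("LocusMap", function(object) {
  ps <- object@probeSites
  need <- c("id", "exon_label", "rank", "specificity", "ligation_pos", "key")
  if (!all(need %in% names(ps)))
    return(paste("probeSites must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(ps$id)) return("duplicated probe ids")
  if (!all(ps$specificity %in% c("gene", "pseudogene", "universal", "reference")))
    return("unknown probe specificity")
  loc <- ps[ps$specificity != "reference", ]
  r <- loc$rank[order(loc$key)]
  if (anyNA(r) || any(diff(r) <= 0))
    return("locus probe ranks must strictly increase 5' to 3'")
  if (any(loc$exon_label == "E10" & loc$specificity != "gene"))
    return("exon 10 is absent from the pseudogene: only gene-specific probes may map there")
  pv <- object@psvCatalog
  if (nrow(pv) > 0 && anyNA(pv$key))
    return("every PSV position must be orderable (non-NA order key)")
  if (nrow(pv) > 0 && any(pv$gene_allele == pv$pseudogene_allele))
    return("PSV alleles must differ between paralogs")
  TRUE
})

#' @describeIn LocusMap probe-site table accessor
#' @param x a \code{LocusMap}.
#' @export
probeSites <- function(x) x@probeSites

#' @describeIn LocusMap PSV catalog accessor
#' @export
psvCatalog <- function(x) x@psvCatalog

#' @describeIn LocusMap ids of locus (non-reference) probe sites, rank order
#' @export
locusSites <- function(x) {
  ps <- x@probeSites[x@probeSites$specificity != "reference", ]
  ps[order(ps$rank), ]
}

#' @describeIn LocusMap ids of off-locus reference (control) probes
#' @export
referenceSites <- function(x)
  x@probeSites$id[x@probeSites$specificity == "reference"]

#' @describeIn LocusMap expected reference copy number per probe (2 for
#'   paralog-specific and reference probes, 4 for universal probes), named
#'   by probe id
#' @export
referenceCopies <- function(x) {
  ps <- x@probeSites
  stats::setNames(ifelse(ps$specificity == "universal", 4L, 2L), ps$id)
}

#' @describeIn LocusMap packaged in-silico allele-specific PCR assays
#' @export
aspAssays <- function(x) x@assays

setMethod("show", "LocusMap", function(object) {
  ps <- object@probeSites
  tab <- table(factor(ps$specificity,
                      c("gene", "pseudogene", "universal", "reference")))
  cat("LocusMap with", nrow(ps), "probe sites (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")\n")
  cat("  PSV catalog:", nrow(object@psvCatalog), "records\n")
  cat("  duplicons:", if (object@dupliconInverted) "inverted," else "direct,",
      object@interdupliconDistanceMb, "Mb apart; pseudogene lacks a",
      object@exon10SpanKb, "kb exon-10 block\n")
  if (length(object@assays))
    cat("  packaged ASP assays:",
        paste(vapply(object@assays, function(a) a@id, ""), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# Haplotype / DiploidGenotype
# ---------------------------------------------------------------------------

#' Haplotype: one physical copy at the gene or pseudogene locus
#'
#' A haplotype is a mosaic of gene- and pseudogene-origin segments over the
#' transcript-ordered probe-site axis, possibly carrying deletions (gene
#' locus only). The crossover model allows at most one origin transition
#' per haplotype unless the conversion-tract flag is set. A breakpoint may
#' additionally be localised below probe resolution through
#' \code{fineAnchors} (the HGVS positions bounding the transition region)
#' and \code{fineMap} (explicit per-PSV origins inside that region, as left
#' by heteroduplex-resolving recombination).
#'
#' @slot locus \code{"gene_locus"} or \code{"pseudogene_locus"}.
#' @slot segments data.frame \code{start}, \code{end}, \code{origin}
#'   (rank intervals tiling the haplotype's axis without overlap).
#' @slot deletions data.frame \code{start}, \code{end} (rank intervals;
#'   gene locus only).
#' @slot conversion logical, tract(s) inserted by gene conversion: relaxes
#'   the single-transition rule at PSV (sub-probe) resolution.
#' @slot fineAnchors character(2) HGVS positions (5' anchor, 3' anchor)
#'   bounding a sub-probe breakpoint region, or NA.
#' @slot fineMap named character: explicit origin per PSV id inside the
#'   breakpoint region / conversion tract.
#' @slot label free-text label.
#' @export
setClass("Haplotype", representation(
  locus = "character",
  segments = "data.frame",
  deletions = "data.frame",
  conversion = "logical",
  fineAnchors = "character",
  fineMap = "character",
  label = "character"
))

setValidity("Haplotype", function(object) {
  if (!object@locus %in% c("gene_locus", "pseudogene_locus"))
    return("locus must be gene_locus or pseudogene_locus")
  seg <- object@segments
  if (nrow(seg) == 0L) return("haplotype needs at least one segment")
  if (!all(seg$origin %in% c("gene", "pseudogene")))
    return("segment origin must be gene or pseudogene")
  if (any(seg$start > seg$end)) return("segment start > end")
  if (nrow(seg) > 1L) {
    if (any(seg$start[-1L] != seg$end[-nrow(seg)] + 1L))
      return("segments must tile the site axis without gaps or overlap")
    ntrans <- sum(seg$origin[-1L] != seg$origin[-nrow(seg)])
    if (ntrans > 1L && !isTRUE(object@conversion))
      return("at most one origin transition unless the conversion flag is set")
  }
  if (nrow(object@deletions) > 0L && object@locus != "gene_locus")
    return("deletions are modelled at the gene locus only")
  TRUE
})

#' Construct a Haplotype
#'
#' @param locus \code{"gene_locus"} or \code{"pseudogene_locus"}.
#' @param segments data.frame with columns \code{start}, \code{end},
#'   \code{origin}.
#' @param deletions optional data.frame with columns \code{start}, \code{end}.
#' @param conversion logical conversion-tract flag.
#' @param fineAnchors optional character(2) HGVS anchors of a sub-probe
#'   breakpoint region.
#' @param fineMap optional named character of per-PSV origins.
#' @param label free-text label.
#' @return a \code{\linkS4class{Haplotype}}.
#' @export
Haplotype <- function(locus, segments,
                      deletions = data.frame(start = integer(), end = integer()),
                      conversion = FALSE,
                      fineAnchors = c(NA_character_, NA_character_),
                      fineMap = character(0),
                      label = "") {
  new("Haplotype", locus = locus,
      segments = as.data.frame(segments),
      deletions = as.data.frame(deletions),
      conversion = conversion, fineAnchors = fineAnchors,
      fineMap = fineMap, label = label)
}

setMethod("show", "Haplotype", function(object) {
  seg <- object@segments
  segtxt <- paste(sprintf("[%d-%d:%s]", seg$start, seg$end,
                          ifelse(seg$origin == "gene", "g", "p")), collapse = "")
  cat("Haplotype", if (nzchar(object@label)) paste0("'", object@label, "'"),
      "at", object@locus, "\n  segments:", segtxt, "\n")
  if (nrow(object@deletions))
    cat("  deletions:", paste(sprintf("[%d-%d]", object@deletions$start,
                                      object@deletions$end), collapse = " "), "\n")
  if (!all(is.na(object@fineAnchors)))
    cat("  sub-probe breakpoint region:", object@fineAnchors[1], "..",
        object@fineAnchors[2], "\n")
})

#' DiploidGenotype: the four haplotypes of one individual
#'
#' Two haplotypes at the gene locus and two at the pseudogene locus.
#' \code{phasing} optionally pairs haplotype indices into two chromosomes.
#'
#' @slot geneHaplotypes list of exactly two gene-locus \code{Haplotype}s.
#' @slot pseudoHaplotypes list of exactly two pseudogene-locus
#'   \code{Haplotype}s.
#' @slot phasing list of two integer pairs (gene index, pseudogene index)
#'   or NULL.
#' @slot label free-text label.
#' @export
setClass("DiploidGenotype", representation(
  geneHaplotypes = "list",
  pseudoHaplotypes = "list",
  phasing = "listOrNULL",
  label = "character"
))

setValidity("DiploidGenotype", function(object) {
  if (length(object@geneHaplotypes) != 2L ||
      length(object@pseudoHaplotypes) != 2L)
    return("a diploid genotype has exactly two haplotypes per locus")
  for (h in object@geneHaplotypes)
    if (!is(h, "Haplotype") || h@locus != "gene_locus")
      return("geneHaplotypes must be gene-locus Haplotype objects")
  for (h in object@pseudoHaplotypes)
    if (!is(h, "Haplotype") || h@locus != "pseudogene_locus")
      return("pseudoHaplotypes must be pseudogene-locus Haplotype objects")
  TRUE
})

#' Construct a DiploidGenotype
#' @param geneHaplotypes list of two gene-locus haplotypes.
#' @param pseudoHaplotypes list of two pseudogene-locus haplotypes.
#' @param phasing optional chromosome pairing.
#' @param label free-text label.
#' @return a \code{\linkS4class{DiploidGenotype}}.
#' @export
DiploidGenotype <- function(geneHaplotypes, pseudoHaplotypes, phasing = NULL,
                            label = "") {
  new("DiploidGenotype", geneHaplotypes = geneHaplotypes,
      pseudoHaplotypes = pseudoHaplotypes, phasing = phasing, label = label)
}

#' @describeIn DiploidGenotype gene-locus haplotypes
#' @param x a \code{DiploidGenotype}.
#' @export
geneHaplotypes <- function(x) x@geneHaplotypes

#' @describeIn DiploidGenotype pseudogene-locus haplotypes
#' @export
pseudoHaplotypes <- function(x) x@pseudoHaplotypes

setMethod("show", "DiploidGenotype", function(object) {
  cat("DiploidGenotype",
      if (nzchar(object@label)) paste0("'", object@label, "'"), "\n")
  cat(" gene locus:\n")
  for (h in object@geneHaplotypes) { cat("  "); show(h) }
  cat(" pseudogene locus:\n")
  for (h in object@pseudoHaplotypes) { cat("  "); show(h) }
})

# ---------------------------------------------------------------------------
# Signal / copy-number containers
# ---------------------------------------------------------------------------

#' CopyNumberProfile: relative signals and integer copy calls per probe
#'
#' @slot sampleId sample identifier.
#' @slot calls data.frame with columns \code{id} (probe id),
#'   \code{relative_signal}, \code{copies} (integer, \code{NA} = NO_CALL),
#'   \code{ref_copies} (2 or 4).
#' @export
setClass("CopyNumberProfile", representation(
  sampleId = "character",
  calls = "data.frame"
))

setValidity("CopyNumberProfile", function(object) {
  cl <- object@calls
  if (!all(c("id", "relative_signal", "copies", "ref_copies") %in% names(cl)))
    return("calls must have columns id, relative_signal, copies, ref_copies")
  ok <- is.na(cl$copies) | (cl$copies >= 0L & cl$copies <= 4L)
  if (!all(ok)) return("copies must be in 0..4 or NA (NO_CALL)")
  if (any(cl$relative_signal < 0)) return("relative signals must be nonnegative")
  TRUE
})

#' @describeIn CopyNumberProfile call table accessor
#' @param x a \code{CopyNumberProfile}.
#' @export
copyCalls <- function(x) x@calls

#' @describeIn CopyNumberProfile sample id accessor
#' @export
sampleId <- function(x) x@sampleId

setMethod("show", "CopyNumberProfile", function(object) {
  cl <- object@calls
  cat("CopyNumberProfile for sample", object@sampleId, "-", nrow(cl),
      "probes,", sum(is.na(cl$copies)), "NO_CALL\n")
})

#' ReferencePanel: qualified reference samples and their signal statistics
#'
#' Holds the intra-sample-scaled signals of the qualified reference members
#' and the per-probe mean/SD used to normalise test samples. Every member
#' passed the 2:2 qualification criterion during panel construction.
#'
#' @slot memberIds character, ids of the panel members.
#' @slot scaledSignals matrix probes x members of median-scaled signals.
#' @slot probeStats data.frame \code{id}, \code{mean}, \code{sd}.
#' @export
setClass("ReferencePanel", representation(
  memberIds = "character",
  scaledSignals = "matrix",
  probeStats = "data.frame"
))

setValidity("ReferencePanel", function(object) {
  if (length(object@memberIds) < 1L) return("panel needs at least one member")
  if (ncol(object@scaledSignals) != length(object@memberIds))
    return("scaledSignals must have one column per member")
  TRUE
})

#' @describeIn ReferencePanel member ids
#' @param x a \code{ReferencePanel}.
#' @export
panelMembers <- function(x) x@memberIds

#' @describeIn ReferencePanel per-probe mean/SD table
#' @export
panelStats <- function(x) x@probeStats

setMethod("show", "ReferencePanel", function(object) {
  cat("ReferencePanel with", length(object@memberIds), "qualified members:",
      paste(object@memberIds, collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# Inference / breakpoint containers
# ---------------------------------------------------------------------------

#' GenotypeSolutionSet: diploid configurations consistent with a profile
#'
#' @slot profileId sample identifier of the interpreted profile.
#' @slot solutions list of \code{DiploidGenotype}, ranked by event count
#'   (breakpoints + deletions), ties broken by fewer deleterious alleles,
#'   then by lexicographic haplotype encoding.
#' @slot events integer vector, total event count per solution.
#' @slot deleterious logical vector, solution contains >= 1 deleterious
#'   gene-locus allele.
#' @slot classification one of \code{normal}, \code{deleterious},
#'   \code{ambiguous}, \code{uninterpretable}.
#' @slot notes character notes (e.g. closest-vector diagnostics).
#' @export
setClass("GenotypeSolutionSet", representation(
  profileId = "character",
  solutions = "list",
  events = "integer",
  deleterious = "logical",
  classification = "character",
  notes = "character"
))

#' @describeIn GenotypeSolutionSet ranked solution list
#' @param x a \code{GenotypeSolutionSet}.
#' @export
solutions <- function(x) x@solutions

#' @describeIn GenotypeSolutionSet classification accessor
#' @export
classification <- function(x) x@classification

#' @describeIn GenotypeSolutionSet per-solution event counts
#' @export
solutionEvents <- function(x) x@events

setMethod("show", "GenotypeSolutionSet", function(object) {
  cat("GenotypeSolutionSet for", object@profileId, "-",
      length(object@solutions), "solution(s), classification:",
      object@classification, "\n")
  if (length(object@events))
    cat("  events:", paste(object@events, collapse = ", "),
        "| deleterious:", paste(substr(object@deleterious, 1, 1),
                                collapse = ", "), "\n")
  if (length(object@notes) && any(nzchar(object@notes)))
    cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

#' BreakpointCall: PSV-delimited breakpoint interval
#'
#' @slot anchorUp HGVS position of the last PSV 5' of which (inclusive) all
#'   PSVs carry the upstream origin; NA when mechanism is \code{none}.
#' @slot anchorDown HGVS position of the first PSV 3' of which (inclusive)
#'   all PSVs carry the downstream origin; NA when mechanism is \code{none}.
#' @slot regionLengthBp inclusive anchor-to-anchor span in bp.
#' @slot interiorPsvs data.frame \code{id}, \code{position}, \code{origin}
#'   of PSVs strictly between the anchors.
#' @slot mechanism \code{crossover}, \code{conversion_tract} or \code{none}.
#' @slot notes character.
#' @export
setClass("BreakpointCall", representation(
  anchorUp = "character",
  anchorDown = "character",
  regionLengthBp = "integer",
  interiorPsvs = "data.frame",
  mechanism = "character",
  notes = "character"
))

#' @describeIn BreakpointCall mechanism accessor
#' @param x a \code{BreakpointCall}.
#' @export
mechanism <- function(x) x@mechanism

#' @describeIn BreakpointCall inclusive breakpoint-region length (bp)
#' @export
regionLength <- function(x) x@regionLengthBp

#' @describeIn BreakpointCall interior discordant PSVs
#' @export
interiorPsvs <- function(x) x@interiorPsvs

setMethod("show", "BreakpointCall", function(object) {
  if (object@mechanism == "none") {
    cat("BreakpointCall: no origin switch (mechanism none)\n")
  } else {
    cat("BreakpointCall:", object@mechanism, "between", object@anchorUp,
        "and", object@anchorDown, "(", object@regionLengthBp, "bp,",
        nrow(object@interiorPsvs), "interior PSVs )\n")
  }
})

#' ASPAssay: in-silico allele-specific PCR assay description
#'
#' Presence/absence logic is origin-based: a primer extends only from a
#' haplotype carrying the required paralog origin at its site. Product
#' lengths are fixture constants of the assay, not computed from primer
#' thermodynamics.
#'
#' @slot id assay identifier.
#' @slot forwardPos,reversePos HGVS positions of the primer 3' ends.
#' @slot forwardOrigin,reverseOrigin required origins (\code{gene} /
#'   \code{pseudogene}).
#' @slot productLengthBp allele-specific product length (bp).
#' @slot controlLengthBp control product length (bp).
#' @export
setClass("ASPAssay", representation(
  id = "character",
  forwardPos = "character",
  forwardOrigin = "character",
  reversePos = "character",
  reverseOrigin = "character",
  productLengthBp = "integer",
  controlLengthBp = "integer"
))

setValidity("ASPAssay", function(object) {
  if (hgvsKey(object@forwardPos) >= hgvsKey(object@reversePos))
    return("forward primer must lie 5' of the reverse primer")
  if (object@productLengthBp <= 0L || object@controlLengthBp <= 0L)
    return("product lengths must be positive")
  TRUE
})

setMethod("show", "ASPAssay", function(object) {
  cat("ASPAssay", object@id, ": forward", object@forwardPos,
      paste0("(", object@forwardOrigin, ")"), "-> reverse", object@reversePos,
      paste0("(", object@reverseOrigin, ");"), object@productLengthBp,
      "bp product,", object@controlLengthBp, "bp control\n")
})

# ---------------------------------------------------------------------------
# Simulation models
# ---------------------------------------------------------------------------

#' PopulationModel: distribution of nondeleterious hybrid alleles
#'
#' Parameterises the background population the synthetic cohort draws from:
#' the fraction of individuals carrying at least one nondeleterious hybrid
#' allele, the allele fraction of exon-14-covering hybrids (the class
#' carrying the pseudogene missense variant), and the breakpoint boundaries
#' (all 3' of exon 12) nondeleterious hybrids may use.
#'
#' @slot pHybridCarrier fraction of individuals with >= 1 hybrid allele.
#' @slot pN775SAllele allele fraction of exon-14-covering hybrids.
#' @slot allowedBreakpoints character, exon labels whose first probe site
#'   starts the paralog-origin tract (\code{"IVS12"}, \code{"E13"},
#'   \code{"E14"}, \code{"E15"}).
#' @export
setClass("PopulationModel", representation(
  pHybridCarrier = "numeric",
  pN775SAllele = "numeric",
  allowedBreakpoints = "character"
))

setValidity("PopulationModel", function(object) {
  if (object@pHybridCarrier < 0 || object@pHybridCarrier > 1)
    return("pHybridCarrier must be in [0, 1]")
  if (object@pN775SAllele < 0 || object@pN775SAllele > 1)
    return("pN775SAllele must be in [0, 1]")
  if (any(!object@allowedBreakpoints %in% c("IVS12", "E13", "E14", "E15")))
    return("nondeleterious breakpoints must lie 3' of the exon-12/13 boundary region")
  TRUE
})

#' Construct a PopulationModel
#' @param pHybridCarrier carrier fraction (default 0.70).
#' @param pN775SAllele allele fraction of exon-14-covering hybrids
#'   (default 0.10).
#' @param allowedBreakpoints allowed tract-start boundaries.
#' @return a \code{\linkS4class{PopulationModel}}.
#' @export
PopulationModel <- function(pHybridCarrier = 0.70, pN775SAllele = 0.10,
                            allowedBreakpoints = c("IVS12", "E13", "E14", "E15")) {
  new("PopulationModel", pHybridCarrier = pHybridCarrier,
      pN775SAllele = pN775SAllele, allowedBreakpoints = allowedBreakpoints)
}

#' NoiseModel: multiplicative lognormal probe-signal noise
#'
#' Each probe signal is multiplied by an independent lognormal factor
#' \code{exp(N(0, sigma))}. With a fixed seed the generated signal tables
#' are reproducible.
#'
#' @slot sigma lognormal scale (>= 0).
#' @slot seed integer seed or NA (use the session RNG stream).
#' @export
setClass("NoiseModel", representation(sigma = "numeric", seed = "integer"))

setValidity("NoiseModel", function(object) {
  if (length(object@sigma) != 1L || is.na(object@sigma) || object@sigma < 0)
    return("sigma must be a single nonnegative number")
  TRUE
})

#' Construct a NoiseModel
#' @param sigma multiplicative lognormal scale (default 0.05).
#' @param seed optional integer seed.
#' @return a \code{\linkS4class{NoiseModel}}.
#' @export
NoiseModel <- function(sigma = 0.05, seed = NA_integer_) {
  new("NoiseModel", sigma = sigma, seed = as.integer(seed))
}
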