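.schema_stop <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("locus_schema_error", "error", "condition")))
}

.require_fields <- function(entry, fields, where) {
  missing <- setdiff(fields, names(entry))
  if (length(missing))
    .schema_stop("locus config block '", where, "' entry ",
                 if (!is.null(entry$id)) paste0("'", entry$id, "' "),
                 "is missing required field(s): ",
                 paste(missing, collapse = ", "))
}

#' Load a two-paralog locus description
#'
#' Reads a structured YAML locus configuration (blocks \code{probe_sites},
#' \code{psv_catalog}, \code{geometry}, optionally \code{exons} and
#' \code{assays}), validates it, assigns transcript-ordered ranks to the
#' locus probe sites and numeric order keys to every position, and returns
#' a \code{\linkS4class{LocusMap}}.
#'
#' Rank assignment sorts locus (non-reference) probe sites by the HGVS
#' order key of their ligation position; co-located paralog-discriminating
#' sites (identical ligation position, different specificity) are ordered
#' gene before pseudogene before universal.
#'
#' @param config path to a YAML locus file, or an already-parsed list.
#' @return a \code{\linkS4class{LocusMap}}.
#' @examples
#' m <- pms2LocusMap()
#' sum(probeSites(m)$specificity == "gene")  # 24
#' @export
loadLocusMap <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (block in c("probe_sites", "psv_catalog", "geometry"))
    if (is.null(cfg[[block]]))
      .schema_stop("locus config is missing required block: ", block)
  geo <- cfg$geometry
  .require_fields(geo, c("exon10_span_kb", "duplicon_inverted",
                         "interduplicon_distance_mb"), "geometry")

  ps <- do.call(rbind, lapply(cfg$probe_sites, function(p) {
    .require_fields(p, c("id", "exon", "specificity"), "probe_sites")
    if (p$specificity != "reference")
      .require_fields(p, "ligation", "probe_sites")
    data.frame(id = p$id, exon_label = p$exon, specificity = p$specificity,
               ligation_pos = if (is.null(p$ligation)) NA_character_ else p$ligation)
  }))
  bad <- setdiff(ps$specificity, c("gene", "pseudogene", "universal", "reference"))
  if (length(bad))
    .schema_stop("probe_sites: unknown specificity value(s): ",
                 paste(bad, collapse = ", "))
  ps$key <- NA_real_
  onloc <- ps$specificity != "reference"
  ps$key[onloc] <- hgvsKey(ps$ligation_pos[onloc])
  specOrder <- match(ps$specificity, c("gene", "pseudogene", "universal"))
  ps$rank <- NA_integer_
  ord <- order(ps$key[onloc], specOrder[onloc])
  ps$rank[onloc][ord] <- seq_len(sum(onloc))

  pv <- do.call(rbind, lapply(cfg$psv_catalog, function(v) {
    .require_fields(v, c("id", "position", "gene_allele", "pseudogene_allele",
                         "kind", "consequence"), "psv_catalog")
    data.frame(id = v$id, position = v$position,
               gene_allele = as.character(v$gene_allele),
               pseudogene_allele = as.character(v$pseudogene_allele),
               kind = v$kind, consequence = v$consequence,
               synthetic_flank = isTRUE(v$synthetic_flank))
  }))
  if (!all(pv$kind %in% c("substitution", "insertion", "deletion", "duplication")))
    .schema_stop("psv_catalog: unknown kind value")
  pv$key <- hgvsKey(pv$position)
  pv <- pv[order(pv$key), , drop = FALSE]
  rownames(pv) <- NULL

  ex <- if (!is.null(cfg$exons)) {
    do.call(rbind, lapply(cfg$exons, function(e)
      data.frame(exon = e$label, cds_start = e$cds_start, cds_end = e$cds_end)))
  } else data.frame(exon = character(), cds_start = integer(), cds_end = integer())

  assays <- lapply(cfg$assays, function(a) {
    .require_fields(a, c("id", "forward_pos", "forward_origin", "reverse_pos",
                         "reverse_origin", "product_length_bp",
                         "control_length_bp"), "assays")
    new("ASPAssay", id = a$id,
        forwardPos = a$forward_pos, forwardOrigin = a$forward_origin,
        reversePos = a$reverse_pos, reverseOrigin = a$reverse_origin,
        productLengthBp = as.integer(a$product_length_bp),
        controlLengthBp = as.integer(a$control_length_bp))
  })

  new("LocusMap", probeSites = ps, psvCatalog = pv, exonTable = ex,
      exon10SpanKb = as.numeric(geo$exon10_span_kb),
      dupliconInverted = isTRUE(geo$duplicon_inverted),
      interdupliconDistanceMb = as.numeric(geo$interduplicon_distance_mb),
      assays = assays)
}

#' Packaged PMS2/PMS2CL locus map
#'
#' Loads the locus description shipped with the package: 24 gene-specific,
#' 5 pseudogene-specific and 5 universal MLPA probe sites, 11 off-locus
#' reference probes, the intron-10/exon-11/exon-14/3'UTR PSV catalog and
#' the packaged intron-10 allele-specific PCR assay.
#'
#' @return a \code{\linkS4class{LocusMap}}.
#' @export
pms2LocusMap <- function() {
  loadLocusMap(system.file("extdata", "pms2_locus.yaml",
                           package = "paralogMLPA", mustWork = TRUE))
}

# --- rank-axis helpers ------------------------------------------------------

# ranks (sorted) of locus sites with a given exon label
.ranksOf <- function(m, labels) {
  ps <- m@probeSites
  sort(ps$rank[!is.na(ps$rank) & ps$exon_label %in% labels])
}

# first rank of the shared (pseudogene-covered) probe region: exon 11 on
.sharedStart <- function(m) min(.ranksOf(m, "E11"))

.nLocusSites <- function(m) sum(m@probeSites$specificity != "reference")

# axis covered by a haplotype at a given locus
.locusAxis <- function(m, locus) {
  if (locus == "gene_locus") c(1L, .nLocusSites(m))
  else c(.sharedStart(m), .nLocusSites(m))
}

# origin of a haplotype at each rank of its axis (NA outside axis/deleted
# handled separately); returns character vector indexed by rank 1..N
.hapOriginByRank <- function(h, m) {
  n <- .nLocusSites(m)
  ori <- rep(NA_character_, n)
  for (i in seq_len(nrow(h@segments)))
    ori[h@segments$start[i]:h@segments$end[i]] <- h@segments$origin[i]
  ori
}

.hapDeletedByRank <- function(h, m) {
  n <- .nLocusSites(m)
  del <- rep(FALSE, n)
  for (i in seq_len(nrow(h@deletions)))
    del[h@deletions$start[i]:h@deletions$end[i]] <- TRUE
  del
}

# per-site contribution (0/1) of one haplotype to every locus probe site,
# named by probe id in probeSites order
.hapContrib <- function(h, m) {
  ps <- m@probeSites[m@probeSites$specificity != "reference", ]
  ori <- .hapOriginByRank(h, m)[ps$rank]
  del <- .hapDeletedByRank(h, m)[ps$rank]
  present <- !is.na(ori) & !del
  contrib <- as.integer(present & (ps$specificity == "universal" |
                                     (ps$specificity == "gene" & ori == "gene") |
                                     (ps$specificity == "pseudogene" & ori == "pseudogene")))
  stats::setNames(contrib, ps$id)
}

#' Noise-free copy vector of a diploid genotype
#'
#' Sums, per probe site, the contributions of all four haplotypes: a
#' haplotype contributes at a site when it covers the site's rank, the site
#' is not deleted, and the segment origin matches the probe's paralog
#' specificity (universal probes bind either origin). Off-locus reference
#' probes are constant at two copies. Pseudogene-origin segments contribute
#' nothing at exon-10 sites (the pseudogene lacks that block): all exon-10
#' probes are gene-specific, so the rule follows from specificity matching.
#'
#' @param g a \code{\linkS4class{DiploidGenotype}}.
#' @param m a \code{\linkS4class{LocusMap}}.
#' @return named integer vector of copies, one entry per probe site in
#'   \code{probeSites(m)} order.
#' @examples
#' m <- pms2LocusMap()
#' expectedCopyVector(makeCaseGenotype("NORMAL", m), m)
#' @export
expectedCopyVector <- function(g, m) {
  stopifnot(is(g, "DiploidGenotype"), is(m, "LocusMap"))
  haps <- c(g@geneHaplotypes, g@pseudoHaplotypes)
  loc <- Reduce(`+`, lapply(haps, .hapContrib, m = m))
  ps <- m@probeSites
  out <- stats::setNames(rep(2L, nrow(ps)), ps$id)
  out[names(loc)] <- as.integer(loc)
  out
}
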