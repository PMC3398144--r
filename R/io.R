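#' Read a probe-signal table
#'
#' Expects a TSV with a header row of probe ids and one row per sample
#' (first column = sample id).
#'
#' @param path TSV file path.
#' @return matrix of raw signals, probes x samples.
#' @export
readSignalTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df[[1]]
  m
}

#' Write a probe-signal table
#'
#' @param signals matrix of raw signals, probes x samples.
#' @param path TSV file path.
#' @return the path, invisibly.
#' @export
writeSignalTSV <- function(signals, path) {
  df <- data.frame(sample = colnames(signals),
                   t(signals), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PSV origin readout
#'
#' Expects columns \code{position}, \code{gene_allele},
#' \code{pseudogene_allele}, \code{observed_allele}; the origin of each
#' site is derived by matching the observed allele against the paralog
#' alleles.
#'
#' @param path TSV file path.
#' @return data.frame with columns \code{position}, \code{origin},
#'   \code{observed_allele}, suitable for \code{\link{mapBreakpoint}}.
#' @export
readPsvReadoutTSV <- function(path) {
  df <- utils::read.delim(path)
  need <- c("position", "gene_allele", "pseudogene_allele", "observed_allele")
  if (!all(need %in% names(df)))
    stop(errorCondition(paste("readout TSV needs columns:",
                              paste(need, collapse = ", ")),
                        class = c("locus_schema_error", "error", "condition")))
  origin <- ifelse(df$observed_allele == df$gene_allele, "gene",
                   ifelse(df$observed_allele == df$pseudogene_allele,
                          "pseudogene", NA_character_))
  if (anyNA(origin))
    stop("observed allele matches neither paralog at: ",
         paste(df$position[is.na(origin)], collapse = ", "), call. = FALSE)
  data.frame(position = df$position, origin = origin,
             observed_allele = df$observed_allele)
}

#' Read an array probe state track
#'
#' Expects a BED-like TSV with columns \code{chrom}, \code{pos},
#' \code{state}.
#'
#' @param path TSV file path.
#' @return data.frame suitable for \code{\link{boundDeletion}}.
#' @export
readProbeTrackTSV <- function(path) {
  df <- utils::read.delim(path)
  if (!all(c("pos", "state") %in% names(df)))
    stop(errorCondition("track TSV needs columns pos, state",
                        class = c("locus_schema_error", "error", "condition")))
  df[order(df$pos), c(intersect("chrom", names(df)), "pos", "state")]
}

#' Write a per-sample JSON report
#'
#' @param report a \code{sampleReport} (from \code{\link{interpretSample}}).
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeSampleReport <- function(report, path) {
  ss <- report$solutionSet
  out <- list(
    sample_id = report$sampleId,
    aberrant = report$aberrant,
    classification = report$classification,
    masking_possible = report$maskingPossible,
    follow_up = report$followUp,
    no_call_sites = report$noCallSites,
    n_solutions = length(solutions(ss)),
    solution_events = solutionEvents(ss),
    solution_set_classification = classification(ss))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
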