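#' @title End-to-end cohort runs and reporting
#' @description Drives the whole pipeline on a simulated or supplied
#'   cohort: reference-candidate generation and panel qualification,
#'   normalisation, copy-number calling, genotype interpretation, and a
#'   copy-number matrix with category labels.
#' @name cli_report
NULL

#' Run the full paralog-aware MLPA pipeline on a cohort
#'
#' Either simulates a cohort (patient archetypes plus population
#' backgrounds) or takes a supplied signal matrix, builds a qualified
#' reference panel from candidate samples, normalises and calls every
#' sample, and interprets each profile. Deterministic under a fixed seed.
#'
#' @param m a \code{\linkS4class{LocusMap}}.
#' @param archetypes character vector of archetype labels simulated as
#'   patients (see \code{\link{makeCaseGenotype}}).
#' @param nBackground number of population background samples added to the
#'   cohort.
#' @param signals optional matrix (probes x samples) of raw patient
#'   signals; when supplied, \code{archetypes}/\code{nBackground} are
#'   ignored and no truth labels are attached.
#' @param pm a \code{\linkS4class{PopulationModel}} for backgrounds and
#'   reference candidates.
#' @param sigma noise SD of the simulated signals.
#' @param nCandidates number of reference candidates drawn.
#' @param minPanel minimum reference-panel size.
#' @param band no-call band for \code{\link{callCopyNumbers}}.
#' @param seed integer seed applied to the whole run.
#' @return object of class \code{cohortReport}: list with \code{samples}
#'   (named list of \code{sampleReport}s), \code{profiles}, \code{summary}
#'   (classification counts), \code{panel}, \code{candidateVerdicts},
#'   \code{truth} (archetype labels, simulated cohorts only) and
#'   \code{parameters}.
#' @examples
#' \donttest{
#' m <- pms2LocusMap()
#' rep <- runCohort(m, archetypes = c("CH8", "CH11", "TR13"),
#'                  nBackground = 10, seed = 1)
#' rep$summary
#' }
#' @export
runCohort <- function(m, archetypes = c("CH8", "CH11", "TR13"),
                      nBackground = 10L, signals = NULL,
                      pm = PopulationModel(), sigma = 0.05,
                      nCandidates = 24L, minPanel = 5L, band = 0.15,
                      seed = NA_integer_) {
  .withSeed(seed, {
    nm <- NoiseModel(sigma = sigma)
    cand <- makeReferenceCandidates(nCandidates, pm, m, nm)
    panel <- buildPanel(cand$signals, m, minSize = minPanel, band = band)
    if (is.null(signals)) {
      genos <- c(lapply(archetypes, makeCaseGenotype, m = m),
                 replicate(nBackground, samplePopulationGenotype(pm, m),
                           simplify = FALSE))
      truth <- c(archetypes, rep("BACKGROUND", nBackground))
      ids <- sprintf("S%02d_%s", seq_along(genos), truth)
      signals <- vapply(genos, simulateProbeSignals, nm = nm, m = m,
                        FUN.VALUE = numeric(nrow(m@probeSites)))
      colnames(signals) <- ids
    } else {
      truth <- NULL
      if (is.null(colnames(signals)))
        colnames(signals) <- sprintf("S%02d", seq_len(ncol(signals)))
    }
    profiles <- lapply(colnames(signals), function(id)
      callCopyNumbers(normalizeSignals(signals[, id], panel, m), m,
                      band = band, sampleId = id))
    names(profiles) <- colnames(signals)
    reports <- lapply(profiles, interpretSample, m = m)
    cls <- vapply(reports, `[[`, "", "classification")
    summary <- table(factor(cls, c("normal", "deleterious", "ambiguous",
                                   "uninterpretable")))
    structure(list(samples = reports, profiles = profiles,
                   summary = summary, panel = panel,
                   candidateVerdicts = attr(panel, "verdicts"),
                   truth = truth,
                   parameters = list(sigma = sigma, band = band,
                                     minPanel = minPanel,
                                     nCandidates = nCandidates, seed = seed)),
              class = "cohortReport")
  })
}

#' @export
print.cohortReport <- function(x, ...) {
  cat("cohortReport:", length(x$samples), "samples;",
      "panel members:", paste(panelMembers(x$panel), collapse = ", "), "\n")
  print(x$summary)
  invisible(x)
}

.cellLabel <- function(copies, specificity, pairTotal, exon, sampleDeleterious) {
  if (is.na(copies)) return("no_call")
  expected <- if (specificity == "universal") 4L else 2L
  if (copies == expected) return("normal")
  if (sampleDeleterious) return("aberrant")
  if (specificity %in% c("gene", "pseudogene") &&
      exon %in% c("E13", "E14", "E15") &&
      !is.na(pairTotal) && pairTotal == 4L) return("uneven_4")
  "aberrant"
}

#' Render a cohort copy-number matrix with category labels
#'
#' One row per sample. Exons 1-7 and 9-10 are reported as grouped columns
#' (single-copy-state regions of the unique gene portion), exon 8 and the
#' shared exon 11-15 region per site, each with a companion label column:
#' \code{normal}, \code{uneven_4} (unequal gene:pseudogene split summing
#' to four copies, the nondeleterious-hybrid signature), \code{aberrant},
#' or \code{no_call}.
#'
#' @param report a \code{cohortReport}.
#' @param m a \code{\linkS4class{LocusMap}}.
#' @return data.frame, one row per sample: grouped/per-site copy columns
#'   plus \code{<column>_label} category columns.
#' @export
renderMatrix <- function(report, m) {
  stopifnot(inherits(report, "cohortReport"))
  if (!length(report$samples)) stop("report is empty", call. = FALSE)
  ps <- locusSites(m)
  grp <- list(E1_E7 = ps$id[ps$exon_label %in% paste0("E", 1:7)],
              E8 = NULL, E9_E10 = ps$id[ps$exon_label %in% c("E9", "E10")])
  persite <- ps$id[ps$exon_label %in% c("E8", "E11", "E12", "IVS12",
                                        "E13", "E14", "E15")]
  # pseudo partner of each paralog-specific site (same exon, other paralog)
  pairTotalOf <- function(calls, id) {
    row <- ps[ps$id == id, ]
    if (!row$specificity %in% c("gene", "pseudogene")) return(NA_integer_)
    other <- setdiff(c("gene", "pseudogene"), row$specificity)
    partner <- ps$id[ps$exon_label == row$exon_label & ps$specificity == other]
    if (!length(partner)) return(NA_integer_)
    own <- calls[calls$id == id, "copies"]
    mate <- calls[calls$id %in% partner, "copies"]
    if (anyNA(c(own, mate))) NA_integer_ else own + as.integer(round(mean(mate)))
  }
  rows <- lapply(names(report$samples), function(sid) {
    rep <- report$samples[[sid]]
    calls <- copyCalls(report$profiles[[sid]])
    sampleDel <- rep$classification == "deleterious"
    out <- list(sample = sid)
    for (gname in c("E1_E7", "E9_E10")) {
      cp <- calls$copies[calls$id %in% grp[[gname]]]
      val <- if (all(is.na(cp))) NA_integer_
             else as.integer(round(mean(cp, na.rm = TRUE)))
      out[[gname]] <- val
      out[[paste0(gname, "_label")]] <-
        if (is.na(val)) "no_call" else if (val == 2L) "normal" else "aberrant"
    }
    for (id in persite) {
      row <- ps[ps$id == id, ]
      cp <- calls$copies[calls$id == id]
      out[[id]] <- cp
      out[[paste0(id, "_label")]] <-
        .cellLabel(cp, row$specificity, pairTotalOf(calls, id),
                   row$exon_label, sampleDel)
    }
    as.data.frame(out)
  })
  do.call(rbind, rows)
}

#' Write the cohort matrix as TSV
#'
#' @param report a \code{cohortReport}.
#' @param m a \code{\linkS4class{LocusMap}}.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeCohortMatrixTSV <- function(report, m, path) {
  utils::write.table(renderMatrix(report, m), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
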