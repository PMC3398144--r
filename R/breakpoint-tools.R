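#' @title PSV-level breakpoint analyses
#' @description Downstream of dosage: breakpoint-interval mapping with
#'   crossover / gene-conversion classification, in-silico allele-specific
#'   PCR, array-probe deletion bounding, and the recombination-clock
#'   generations estimate.
#' @name breakpoint_tools
NULL

#' Map a recombination breakpoint from a PSV origin readout
#'
#' Given the ordered origins of the paralog-discriminating sites along an
#' amplicon, the breakpoint region is delimited by the last position at or
#' 5' of which every PSV carries the upstream origin (inclusive) and the
#' first position at or 3' of which every PSV carries the downstream origin
#' (inclusive). PSVs strictly between the anchors may interleave origins -
#' the footprint of double-Holliday-junction resolution.
#'
#' Mechanism: \code{crossover} when the readout starts and ends with
#' different origins (durable switch); \code{conversion_tract} when it
#' starts and ends with the same origin but contains discordant interior
#' runs (nonreciprocal insertion); \code{none} when all origins agree
#' (anchors are then undefined and reported as NA, not an error).
#'
#' @param readout data.frame with columns \code{position} (HGVS) and
#'   \code{origin} (\code{gene} / \code{pseudogene}), plus optionally
#'   \code{id}; rows in 5'-to-3' order (re-ordered by position key if not).
#' @return a \code{\linkS4class{BreakpointCall}}.
#' @examples
#' m <- pms2LocusMap()
#' g <- makeCaseGenotype("TR13", m)
#' ro <- simulatePsvReadout(geneHaplotypes(g)[[1]], c(11, 13), m)
#' mapBreakpoint(ro)
#' @export
mapBreakpoint <- function(readout) {
  stopifnot(is.data.frame(readout), nrow(readout) >= 2L,
            all(c("position", "origin") %in% names(readout)))
  readout <- readout[order(hgvsKey(readout$position)), , drop = FALSE]
  ori <- readout$origin
  if (!all(ori %in% c("gene", "pseudogene")))
    stop("origins must be 'gene' or 'pseudogene'", call. = FALSE)
  if (length(unique(ori)) == 1L)
    return(new("BreakpointCall", anchorUp = NA_character_,
               anchorDown = NA_character_, regionLengthBp = NA_integer_,
               interiorPsvs = readout[0, , drop = FALSE], mechanism = "none",
               notes = "all PSVs share one origin; no breakpoint"))
  a <- ori[1]; b <- ori[length(ori)]
  up <- max(which(cumsum(ori != a) == 0L))          # end of initial a-run
  down <- min(which(rev(cumsum(rev(ori != b))) == 0L))  # start of final b-run
  anchorUp <- readout$position[up]
  anchorDown <- readout$position[down]
  interior <- readout[seq_len(nrow(readout)) > up &
                        seq_len(nrow(readout)) < down, , drop = FALSE]
  len <- tryCatch(hgvsSpanLength(anchorUp, anchorDown),
                  error = function(e) NA_integer_)
  mech <- if (a != b) "crossover" else "conversion_tract"
  notes <- if (mech == "conversion_tract")
    sprintf("discordant tract of %d site(s) flanked by %s origin on both sides",
            sum(interior$origin != a), a)
  else sprintf("durable %s -> %s origin switch", a, b)
  new("BreakpointCall", anchorUp = anchorUp, anchorDown = anchorDown,
      regionLengthBp = as.integer(len), interiorPsvs = interior,
      mechanism = mech, notes = notes)
}

#' In-silico allele-specific PCR on a diploid genotype
#'
#' Origin-based amplification logic: the allele-specific product appears
#' iff at least one single haplotype carries the required paralog origin at
#' both primer sites in 5'-to-3' order (an allele-specific primer only
#' extends from its matching origin). The control product appears whenever
#' at least one haplotype provides template in the control region (exon 15,
#' nonspecific primers).
#'
#' @param g a \code{\linkS4class{DiploidGenotype}}.
#' @param assay an \code{\linkS4class{ASPAssay}}; defaults to the packaged
#'   intron-10 crossover assay when the map carries one.
#' @param m a \code{\linkS4class{LocusMap}}.
#' @return data.frame with columns \code{product}, \code{length_bp},
#'   \code{present}, \code{template} (label of an amplifying haplotype or
#'   NA).
#' @examples
#' m <- pms2LocusMap()
#' insilicoASP(makeCaseGenotype("TR13", m), aspAssays(m)[[1]], m)
#' @export
insilicoASP <- function(g, assay, m) {
  stopifnot(is(g, "DiploidGenotype"), is(assay, "ASPAssay"))
  ps <- locusSites(m)
  kF <- hgvsKey(assay@forwardPos); kR <- hgvsKey(assay@reversePos)
  if (kF < min(ps$key) - 2 * .HGVS_BASE || kR > max(ps$key) + 2 * .HGVS_BASE)
    stop(errorCondition("assay primer sites lie outside the locus map",
                        class = c("range_error", "error", "condition")))
  haps <- c(g@geneHaplotypes, g@pseudoHaplotypes)
  amplifies <- vapply(haps, function(h) {
    isTRUE(.hapOriginAtKey(h, m, kF) == assay@forwardOrigin) &&
      isTRUE(.hapOriginAtKey(h, m, kR) == assay@reverseOrigin)
  }, logical(1))
  e15 <- .ranksOf(m, "E15")
  hasControl <- vapply(haps, function(h) {
    ax <- range(c(h@segments$start, h@segments$end))
    del <- .hapDeletedByRank(h, m)
    any(e15 >= ax[1] & e15 <= ax[2] & !del[e15])
  }, logical(1))
  template <- function(ok) if (any(ok)) {
    lab <- haps[[which(ok)[1]]]@label
    if (nzchar(lab)) lab else "unlabelled haplotype"
  } else NA_character_
  data.frame(
    product = c("allele_specific", "control"),
    length_bp = c(assay@productLengthBp, assay@controlLengthBp),
    present = c(any(amplifies), any(hasControl)),
    template = c(template(amplifies), template(hasControl)))
}

#' Bound a deletion from an array probe state track
#'
#' Given ordered (coordinate, state) probe observations with a contiguous
#' run of deleted probes, returns the innermost (minimal) and outermost
#' (maximal) deletion sizes and the two breakpoint-containing intervals:
#' the distal interval between the last retained probe and the first
#' deleted probe, and the proximal interval between the last deleted probe
#' and the next retained probe.
#'
#' @param track data.frame with columns \code{pos} (strictly increasing
#'   integer coordinates) and \code{state} (\code{retained} /
#'   \code{deleted}).
#' @return list with \code{min_size_bp}, \code{max_size_bp},
#'   \code{distal_interval}, \code{proximal_interval} and
#'   \code{one_sided} (TRUE when the deleted run touches a track edge);
#'   an empty list (length 0) when the track contains no deleted probe.
#' @examples
#' boundDeletion(data.frame(pos = c(0, 100, 200),
#'                          state = c("retained", "deleted", "retained")))
#' @export
boundDeletion <- function(track) {
  stopifnot(is.data.frame(track), all(c("pos", "state") %in% names(track)))
  if (is.unsorted(track$pos, strictly = TRUE))
    stop("track coordinates must be strictly increasing", call. = FALSE)
  del <- track$state == "deleted"
  if (!any(del)) return(structure(list(), class = "deletionBounds"))
  r <- rle(del)
  if (sum(r$values) > 1L)
    stop("track contains more than one deleted run", call. = FALSE)
  i1 <- min(which(del)); i2 <- max(which(del))
  oneSided <- i1 == 1L || i2 == nrow(track)
  distal <- c(if (i1 > 1L) track$pos[i1 - 1L] else NA_real_, track$pos[i1])
  proximal <- c(track$pos[i2], if (i2 < nrow(track)) track$pos[i2 + 1L] else NA_real_)
  structure(list(
    min_size_bp = as.numeric(track$pos[i2] - track$pos[i1]),
    max_size_bp = as.numeric(proximal[2] - distal[1]),
    distal_interval = as.numeric(distal),
    proximal_interval = as.numeric(proximal),
    one_sided = oneSided), class = "deletionBounds")
}

#' @export
print.deletionBounds <- function(x, ...) {
  if (!length(x)) { cat("no deleted run in track\n"); return(invisible(x)) }
  cat(sprintf("deletion: %s - %s bp%s\n", format(x$min_size_bp, big.mark = ","),
              format(x$max_size_bp, big.mark = ","),
              if (x$one_sided) " (one-sided bounds)" else ""))
  cat("  distal breakpoint interval:  ", paste(x$distal_interval, collapse = " .. "), "\n")
  cat("  proximal breakpoint interval:", paste(x$proximal_interval, collapse = " .. "), "\n")
  invisible(x)
}

#' Expected generations until one recombination in an interval
#'
#' Under the small-interval approximation the per-meiosis recombination
#' fraction of an interval of \code{distanceMb} megabases at
#' \code{rateCMperMb} centimorgan per megabase is
#' \code{distanceMb * rateCMperMb / 100}; the expected waiting time until
#' one recombination is its reciprocal, in generations.
#'
#' @param distanceMb interval size in Mb (> 0).
#' @param rateCMperMb recombination rate in cM/Mb (> 0).
#' @return expected number of generations (exact reciprocal, unrounded).
#' @examples
#' expectedGenerations(0.7, 1.1)  # ~130
#' @export
expectedGenerations <- function(distanceMb, rateCMperMb) {
  if (!is.numeric(distanceMb) || !is.numeric(rateCMperMb) ||
      distanceMb <= 0 || rateCMperMb <= 0)
    stop(errorCondition("distance and rate must both be positive",
                        class = c("parameter_error", "error", "condition")))
  if (distanceMb * rateCMperMb >= 50)
    stop(errorCondition("interval exceeds the small-interval approximation (>= 50 cM)",
                        class = c("parameter_error", "error", "condition")))
  100 / (distanceMb * rateCMperMb)
}
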