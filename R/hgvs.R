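#' @title HGVS-style coding/intronic coordinate arithmetic
#'
#' @description
#' Probe ligation sites and paralogous sequence variants (PSVs) at the
#' PMS2/PMS2CL locus are published as HGVS-style coding positions with
#' optional intronic offsets (e.g. \code{c.1145-942}, \code{c.2174+1097}) or
#' 3'UTR positions (\code{c.*92}). These helpers parse such positions, place
#' them on a single transcript-ordered axis, and compute inclusive spans.
#'
#' Positions are compared through a numeric order key: the anchoring coding
#' base dominates, the intronic offset breaks ties (negative offsets, which
#' count back from the first base of the downstream exon, sort immediately
#' before that base; positive offsets sort immediately after the upstream
#' exon's last base). 3'UTR positions sort after all coding positions.
#' @name hgvs
NULL

# offset weight: one coding base spans 1e6 key units, so intronic offsets up
# to +/- 499999 nt order correctly within their anchoring intron
.HGVS_BASE <- 1e6
.HGVS_UTR3 <- 50000L  # pseudo-anchor added to 3'UTR positions

.hgvs_strip <- function(x) {
  x <- sub("^c\\.", "", trimws(x))
  # drop any trailing variant description (dupA, delTA, A>G, insC ...)
  sub("^(\\*?[0-9]+([+-][0-9]+)?(_\\*?[0-9]+([+-][0-9]+)?)?).*$", "\\1", x)
}

.hgvs_parse_simple <- function(tok) {
  m <- regmatches(tok, regexec("^(\\*?)([0-9]+)([+-][0-9]+)?$", tok))[[1]]
  if (length(m) == 0L)
    stop("unsupported HGVS position: '", tok, "'", call. = FALSE)
  utr3 <- m[2] == "*"
  anchor <- as.integer(m[3])
  offset <- if (nzchar(m[4])) as.integer(m[4]) else 0L
  list(anchor = anchor, offset = offset, utr3 = utr3)
}

.hgvs_key_one <- function(p) {
  a <- p$anchor + if (p$utr3) .HGVS_UTR3 else 0L
  a * .HGVS_BASE + p$offset
}

#' Parse an HGVS-style position
#'
#' Accepts simple positions (\code{c.100}), intron-offset positions
#' (\code{c.1145-942}, \code{c.803+384}), 3'UTR positions (\code{c.*92}) and
#' two-coordinate ranges (\code{c.1145-880_1145-879}); a trailing variant
#' description (\code{dupA}, \code{A>G}, ...) is ignored.
#'
#' @param x character vector of HGVS-style positions.
#' @return A data.frame with one row per input: \code{anchor}, \code{offset},
#'   \code{utr3} for the 5' coordinate, the same with suffix \code{2} for the
#'   3' coordinate (equal to the first for simple positions), and numeric
#'   order keys \code{key} (5') and \code{key2} (3').
#' @examples
#' hgvsParse(c("c.1145-942", "c.*92dupA", "c.1863_1864delTA"))
#' @export
hgvsParse <- function(x) {
  toks <- .hgvs_strip(x)
  out <- lapply(toks, function(tok) {
    parts <- strsplit(tok, "_", fixed = TRUE)[[1]]
    p1 <- .hgvs_parse_simple(parts[1])
    p2 <- if (length(parts) > 1L) .hgvs_parse_simple(parts[2]) else p1
    k1 <- .hgvs_key_one(p1); k2 <- .hgvs_key_one(p2)
    if (k2 < k1) { tmp <- p1; p1 <- p2; p2 <- tmp; tmp <- k1; k1 <- k2; k2 <- tmp }
    data.frame(anchor = p1$anchor, offset = p1$offset, utr3 = p1$utr3,
               anchor2 = p2$anchor, offset2 = p2$offset, utr32 = p2$utr3,
               key = k1, key2 = k2)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Transcript-order key of an HGVS position
#'
#' @param x character vector of HGVS-style positions.
#' @param end use the 3' coordinate of a range instead of the 5' one.
#' @return numeric vector of order keys; comparing keys orders positions 5'
#'   to 3' along the transcript.
#' @export
hgvsKey <- function(x, end = FALSE) {
  p <- hgvsParse(x)
  if (end) p$key2 else p$key
}

#' Inclusive nucleotide span between two HGVS positions
#'
#' Returns the inclusive base-pair count between two positions. Supported
#' pairs: two coding (or two 3'UTR) positions without offsets, or two
#' positions anchored to the same exon boundary with offsets of the same
#' sign (both counting into the same intron). Distances across an intron
#' whose length is not encoded in the coordinates are refused.
#'
#' The arguments may be given in either orientation; ranges contribute their
#' outermost coordinates.
#'
#' @param a,b HGVS-style positions.
#' @return integer, inclusive span in bp.
#' @examples
#' hgvsSpanLength("c.1145-942", "c.1145-790")  # 153
#' hgvsSpanLength("c.100", "c.100")            # 1
#' @export
hgvsSpanLength <- function(a, b) {
  pa <- hgvsParse(a); pb <- hgvsParse(b)
  if (pa$key > pb$key2) { tmp <- pa; pa <- pb; pb <- tmp }  # orient 5' -> 3'
  # 5' end of a, 3' end of b
  a1 <- list(anchor = pa$anchor, offset = pa$offset, utr3 = pa$utr3)
  b1 <- list(anchor = pb$anchor2, offset = pb$offset2, utr3 = pb$utr32)
  if (a1$utr3 != b1$utr3)
    stop("unsupported coordinates: cannot span the coding/3'UTR junction",
         call. = FALSE)
  if (a1$offset == 0L && b1$offset == 0L)
    return(abs(b1$anchor - a1$anchor) + 1L)
  if (a1$anchor == b1$anchor && sign(a1$offset) * sign(b1$offset) >= 0)
    return(abs(a1$offset - b1$offset) + 1L)
  stop("unsupported coordinates: positions lie in unanchored intronic ",
       "frames ('", a, "' vs '", b, "')", call. = FALSE)
}
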