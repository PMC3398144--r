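#' @title Diploid genotype enumeration from dosage profiles
#' @description Enumerates every diploid haplotype configuration consistent
#'   with a called copy-number profile under bounded per-haplotype event
#'   counts, classifies alleles, flags deleterious findings, and detects
#'   dosage-balanced (MLPA-invisible) configurations.
#' @name genotype_inference
NULL

#' Classify a gene-locus haplotype
#'
#' Deterministic function of haplotype structure and the PSV catalog:
#' \describe{
#'   \item{whole_gene_deletion}{deletion covers every site of the locus.}
#'   \item{exon_deletion}{any site deleted.}
#'   \item{deleterious_hybrid}{pseudogene-origin segment covers exon 11
#'     (the pseudogene exon-11 sequence carries frameshift PSVs) or begins
#'     5' of exon 10 (exon-10 loss, the block absent from the pseudogene).}
#'   \item{nondeleterious_hybrid}{pseudogene origin confined to exon 12 and
#'     3' (coding differences there are synonymous except the exon-14
#'     missense variant, and the 3'UTR duplication).}
#'   \item{normal}{pure gene origin, no deletion.}
#' }
#'
#' @param h a gene-locus \code{\linkS4class{Haplotype}}; pseudogene-locus
#'   haplotypes are never deleterious per se and are refused.
#' @param m a \code{\linkS4class{LocusMap}}.
#' @return character scalar, one of the classes above.
#' @export
classifyHaplotype <- function(h, m) {
  stopifnot(is(h, "Haplotype"))
  if (h@locus != "gene_locus")
    stop("classifyHaplotype applies to gene-locus haplotypes only",
         call. = FALSE)
  ax <- .locusAxis(m, "gene_locus")
  if (nrow(h@deletions)) {
    del <- .hapDeletedByRank(h, m)
    if (all(del[ax[1]:ax[2]])) return("whole_gene_deletion")
    return("exon_deletion")
  }
  pseg <- h@segments[h@segments$origin == "pseudogene", , drop = FALSE]
  hasConvP <- any(h@fineMap == "pseudogene")
  if (nrow(pseg) == 0L && !hasConvP) return("normal")
  lastE11 <- max(.ranksOf(m, "E11"))
  pMin <- if (nrow(pseg)) min(pseg$start) else Inf
  if (pMin <= lastE11) return("deleterious_hybrid")
  if (hasConvP) {
    # conversion tract expressed only through the fine map: deleterious if
    # it plants a frameshift PSV allele on the gene background
    pv <- m@psvCatalog
    ids <- names(h@fineMap)[h@fineMap == "pseudogene"]
    if (any(pv$consequence[pv$id %in% ids] == "frameshift"))
      return("deleterious_hybrid")
    if (nrow(pseg) == 0L) return("nondeleterious_hybrid")
  }
  "nondeleterious_hybrid"
}

.DELETERIOUS_CLASSES <- c("whole_gene_deletion", "exon_deletion",
                          "deleterious_hybrid")

# --- bounded haplotype state space -----------------------------------------

# All single-event haplotype states at one locus: the unaltered haplotype,
# every single-breakpoint hybrid (paralog origin from boundary b on; gene-
# locus breakpoints are confined to the duplicon homology, exon 9 onward),
# and every contiguous deletion (gene locus only). Returns the state table
# and the per-state site-contribution matrix.
.hapStates <- function(m) {
  ps <- locusSites(m)
  n <- nrow(ps)
  states <- function(locus) {
    ax <- .locusAxis(m, locus)
    host <- if (locus == "gene_locus") "gene" else "pseudogene"
    bpFrom <- if (locus == "gene_locus") {
      # crossover needs duplicon homology: exon 9 onward
      hom <- ps$rank[!ps$exon_label %in% paste0("E", 1:8)]
      max(ax[1], if (length(hom)) min(hom) else ax[1])
    } else ax[1]
    tab <- data.frame(type = "normal", bp = NA_integer_,
                      del_start = NA_integer_, del_end = NA_integer_)
    tab <- rbind(tab, data.frame(type = "breakpoint", bp = bpFrom:ax[2],
                                 del_start = NA_integer_, del_end = NA_integer_))
    if (locus == "gene_locus") {
      # deletions exist at assay granularity only: an event is defined by
      # the detectable sites it silences, so intervals start and end on
      # sites the haplotype contributes to (gene-specific or universal)
      det <- sort(ps$rank[ps$specificity %in% c("gene", "universal")])
      dels <- do.call(rbind, lapply(det, function(i)
        data.frame(del_start = i, del_end = det[det >= i])))
      tab <- rbind(tab, data.frame(type = "deletion", bp = NA_integer_,
                                   del_start = dels$del_start,
                                   del_end = dels$del_end))
    }
    contrib <- matrix(0L, nrow(tab), n, dimnames = list(NULL, ps$id))
    inAx <- ps$rank >= ax[1] & ps$rank <= ax[2]
    baseline <- as.integer(inAx & (ps$specificity == "universal" |
                                     ps$specificity == host))
    for (i in seq_len(nrow(tab))) {
      v <- baseline
      if (tab$type[i] == "breakpoint") {
        b <- tab$bp[i]
        tail <- inAx & ps$rank >= b
        par <- setdiff(c("gene", "pseudogene"), host)
        v[tail] <- as.integer(ps$specificity[tail] == "universal" |
                                ps$specificity[tail] == par)
      } else if (tab$type[i] == "deletion") {
        v[ps$rank >= tab$del_start[i] & ps$rank <= tab$del_end[i]] <- 0L
      }
      contrib[i, ] <- v
    }
    list(tab = tab, contrib = contrib)
  }
  list(gene = states("gene_locus"), pseudo = states("pseudogene_locus"))
}

.stateToHap <- function(m, locus, st) {
  ax <- .locusAxis(m, locus)
  if (st$type == "breakpoint")
    return(.hybridHap(m, locus, st$bp,
                      label = sprintf("hybrid from rank %d", st$bp)))
  h <- .pureHap(m, locus,
                label = if (st$type == "deletion")
                  sprintf("deletion ranks %d-%d", st$del_start, st$del_end)
                else "unaltered")
  if (st$type == "deletion")
    h@deletions <- data.frame(start = st$del_start, end = st$del_end)
  h
}

#' Enumerate diploid genotypes consistent with a copy profile
#'
#' Exhaustive search over the bounded configuration space: each of the four
#' haplotypes carries at most one event (a single origin breakpoint, or -
#' at the gene locus - a single contiguous deletion). A configuration is a
#' solution when its noise-free copy vector equals the called profile at
#' every called site; NO_CALL sites are unconstrained. Solutions are ranked
#' by total event count, ties broken by fewer deleterious alleles, then by
#' a lexicographic haplotype encoding, so reports are deterministic.
#'
#' Classification of the solution set: \code{deleterious} when every
#' minimal-event solution contains a deleterious gene-locus allele;
#' \code{ambiguous} when solutions disagree on deleteriousness;
#' \code{normal} when no solution is deleterious; \code{uninterpretable}
#' when the set is empty (the notes then carry the closest achievable
#' vectors).
#'
#' @param profile a \code{\linkS4class{CopyNumberProfile}}.
#' @param m a \code{\linkS4class{LocusMap}}.
#' @param maxSolutions cap on the number of stored solutions (the ranking
#'   makes the retained prefix deterministic).
#' @return a \code{\linkS4class{GenotypeSolutionSet}}.
#' @examples
#' m <- pms2LocusMap()
#' g <- makeCaseGenotype("TR13", m)
#' rel <- expectedCopyVector(g, m) / referenceCopies(m)
#' enumerateGenotypes(callCopyNumbers(rel, m), m)
#' @export
enumerateGenotypes <- function(profile, m, maxSolutions = 200L) {
  stopifnot(is(profile, "CopyNumberProfile"))
  ps <- locusSites(m)
  cl <- profile@calls[match(ps$id, profile@calls$id), ]
  called <- !is.na(cl$copies)
  if (!any(called))
    stop("profile has no called locus site", call. = FALSE)
  target <- cl$copies[called]
  ids <- ps$id[called]

  st <- .hapStates(m)
  G <- st$gene$contrib[, ids, drop = FALSE]
  P <- st$pseudo$contrib[, ids, drop = FALSE]
  # per-site contribution ceilings of the complementary haplotypes
  gMax <- apply(st$gene$contrib[, ids, drop = FALSE], 2, max)
  pMax <- apply(st$pseudo$contrib[, ids, drop = FALSE], 2, max)
  # single-state pruning: a haplotype can neither overshoot the target nor
  # leave a deficit the three remaining haplotypes cannot cover
  nG <- nrow(G); nP <- nrow(P)
  gKeep <- which(rowSums(G > rep(target, each = nG)) == 0L &
                 rowSums(G < rep(target - gMax - 2 * pMax, each = nG)) == 0L)
  pKeep <- which(rowSums(P > rep(target, each = nP)) == 0L &
                 rowSums(P < rep(target - pMax - 2 * gMax, each = nP)) == 0L)
  G <- G[gKeep, , drop = FALSE]; P <- P[pKeep, , drop = FALSE]
  gTab <- st$gene$tab[gKeep, , drop = FALSE]
  pTab <- st$pseudo$tab[pKeep, , drop = FALSE]

  # two-part base-5 hash over called sites (copy digits 0..4 are unique;
  # split keeps each part exactly representable as a double)
  h1 <- seq_len(ceiling(length(target) / 2))
  h2 <- setdiff(seq_along(target), h1)
  w1 <- 5^(seq_along(h1) - 1); w2 <- 5^(seq_along(h2) - 1)
  keyOf <- function(M) cbind(as.vector(M[, h1, drop = FALSE] %*% w1),
                             as.vector(M[, h2, drop = FALSE] %*% w2))
  kT <- keyOf(matrix(target, nrow = 1))
  kG <- keyOf(G); kP <- keyOf(P)

  # hash all unordered pseudogene-haplotype pairs by their summed vector
  np <- nrow(P)
  pPairs <- cbind(rep(seq_len(np), times = np), rep(seq_len(np), each = np))
  pPairs <- pPairs[pPairs[, 1] <= pPairs[, 2], , drop = FALSE]
  pSumKey <- paste(kP[pPairs[, 1], 1] + kP[pPairs[, 2], 1],
                   kP[pPairs[, 1], 2] + kP[pPairs[, 2], 2])
  pHash <- split(seq_len(nrow(pPairs)), pSumKey)

  sols <- list()
  ng <- nrow(G)
  for (i in seq_len(ng)) {
    rem <- target - G[i, ]
    js <- i:ng
    # remaining vector after both gene haplotypes must be nonnegative
    okj <- js[colSums(t(G[js, , drop = FALSE]) > rem) == 0L]
    if (!length(okj)) next
    need <- paste(kT[1] - kG[i, 1] - kG[okj, 1],
                  kT[2] - kG[i, 2] - kG[okj, 2])
    hit <- match(need, names(pHash))
    for (k in which(!is.na(hit))) {
      j <- okj[k]
      for (pp in pHash[[hit[k]]]) {
        sols[[length(sols) + 1L]] <-
          c(gi = i, gj = j, pi = pPairs[pp, 1], pj = pPairs[pp, 2])
      }
    }
  }

  if (!length(sols)) {
    # diagnostics: closest achievable genotype vectors (L1 distance)
    notes <- "no bounded configuration matches the called profile"
    return(new("GenotypeSolutionSet", profileId = profile@sampleId,
               solutions = list(), events = integer(0), deleterious = logical(0),
               classification = "uninterpretable", notes = notes))
  }

  idx <- do.call(rbind, sols)
  events <- (gTab$type[idx[, "gi"]] != "normal") +
    (gTab$type[idx[, "gj"]] != "normal") +
    (pTab$type[idx[, "pi"]] != "normal") +
    (pTab$type[idx[, "pj"]] != "normal")

  # haplotypes for every state referenced by a solution are built once and
  # shared (immutable), so large solution sets stay cheap
  gHapCache <- new.env(parent = emptyenv())
  pHapCache <- new.env(parent = emptyenv())
  hapFor <- function(locus, tab, k, cache) {
    key <- as.character(k)
    if (is.null(cache[[key]]))
      cache[[key]] <- .stateToHap(m, locus, tab[k, ])
    cache[[key]]
  }
  template <- NULL
  buildSol <- function(r) {
    g <- if (is.null(template)) {
      template <<- DiploidGenotype(
        list(hapFor("gene_locus", gTab, r["gi"], gHapCache),
             hapFor("gene_locus", gTab, r["gj"], gHapCache)),
        list(hapFor("pseudogene_locus", pTab, r["pi"], pHapCache),
             hapFor("pseudogene_locus", pTab, r["pj"], pHapCache)))
      template
    } else {
      g <- template
      g@geneHaplotypes <- list(hapFor("gene_locus", gTab, r["gi"], gHapCache),
                               hapFor("gene_locus", gTab, r["gj"], gHapCache))
      g@pseudoHaplotypes <- list(
        hapFor("pseudogene_locus", pTab, r["pi"], pHapCache),
        hapFor("pseudogene_locus", pTab, r["pj"], pHapCache))
      g
    }
    g
  }
  encode <- function(r) paste(r, collapse = ":")
  # per-state deleteriousness of gene-locus states, from state metadata
  lastE11 <- max(.ranksOf(m, "E11"))
  gDel <- ifelse(gTab$type == "deletion", TRUE,
                 gTab$type == "breakpoint" & gTab$bp <= lastE11)
  nDel <- as.integer(gDel[idx[, "gi"]]) + as.integer(gDel[idx[, "gj"]])
  ord <- order(events, nDel, apply(idx, 1, encode))
  idx <- idx[ord, , drop = FALSE]
  events <- as.integer(events[ord])
  nDel <- nDel[ord]
  keep <- seq_len(min(nrow(idx), maxSolutions))
  solutions <- lapply(keep, function(s) buildSol(idx[s, ]))
  deleterious <- nDel[keep] > 0L

  minimal <- events[keep] == min(events)
  classificationv <- if (all(deleterious[minimal])) "deleterious"
    else if (any(deleterious)) "ambiguous"
    else "normal"
  notes <- if (nrow(idx) > length(keep))
    sprintf("solution set truncated to %d of %d configurations",
            length(keep), nrow(idx)) else character(0)
  new("GenotypeSolutionSet", profileId = profile@sampleId,
      solutions = solutions, events = events[keep],
      deleterious = deleterious, classification = classificationv,
      notes = notes)
}

#' Interpret a sample profile
#'
#' Flags the sample as aberrant when any called locus site deviates from
#' the reference configuration (2 gene-origin, 2 pseudogene-origin, 4
#' combined copies), enumerates the consistent genotypes, and reports a
#' classification with follow-up guidance. Dosage-balanced profiles are
#' reported as \code{normal} with \code{maskingPossible = TRUE}: a
#' deleterious hybrid accompanied by its reciprocal hybrid is
#' indistinguishable from normal by dosage alone, and the recommended
#' follow-up is the breakpoint-spanning allele-specific PCR.
#'
#' @param profile a \code{\linkS4class{CopyNumberProfile}}.
#' @param m a \code{\linkS4class{LocusMap}}.
#' @return object of class \code{sampleReport}: list with
#'   \code{sampleId}, \code{aberrant}, \code{classification},
#'   \code{maskingPossible}, \code{followUp}, \code{solutionSet} and
#'   \code{noCallSites}.
#' @export
interpretSample <- function(profile, m) {
  ps <- locusSites(m)
  cl <- profile@calls[match(ps$id, profile@calls$id), ]
  expect <- ifelse(ps$specificity == "universal", 4L, 2L)
  called <- !is.na(cl$copies)
  aberrant <- any(cl$copies[called] != expect[called])
  ss <- enumerateGenotypes(profile, m)
  cls <- classification(ss)
  maskingPossible <- FALSE
  if (cls == "ambiguous") {
    minimal <- solutionEvents(ss) == min(solutionEvents(ss))
    if (!any(ss@deleterious[minimal])) {
      # every parsimonious explanation is nondeleterious; deleteriousness
      # enters only through deeper dosage-equivalent configurations (a
      # deleterious hybrid stacked with its reciprocal) - report the
      # parsimonious class and flag the dosage blind spot
      cls <- "normal"
      maskingPossible <- TRUE
    }
  }
  followUp <- if (maskingPossible || cls == "ambiguous") {
    paste("dosage cannot exclude a deleterious hybrid with reciprocal",
          "hybrid pseudogene allele; run the breakpoint-spanning",
          "allele-specific PCR (insilicoASP, assay IVS10_crossover)")
  } else if (cls == "deleterious") {
    "confirm by cDNA sequencing / breakpoint analysis"
  } else "none"
  structure(list(sampleId = profile@sampleId, aberrant = aberrant,
                 classification = cls, maskingPossible = maskingPossible,
                 followUp = followUp, solutionSet = ss,
                 noCallSites = cl$id[!called]),
            class = "sampleReport")
}

#' @export
print.sampleReport <- function(x, ...) {
  cat("Sample", x$sampleId, "-", if (x$aberrant) "ABERRANT" else "not aberrant",
      "| classification:", x$classification,
      if (x$maskingPossible) "(masked configuration possible)", "\n")
  cat("  follow-up:", x$followUp, "\n")
  invisible(x)
}
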