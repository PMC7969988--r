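# Cross-dataset subgroup matching from marker evidence: shared-marker
# counts, enrichment magnitude, and marker specificity combined into an
# additive score; reciprocal best hits with a tie band give the consensus
# correspondence.

#' Shared-marker overlap matrix
#'
#' Entry (a, b) counts the retained marker genes shared (by exact gene-name
#' match) between subgroup a of dataset A and subgroup b of dataset B.
#' Marker genes of one table never seen anywhere in the other are counted
#' in the `unmatched_a` / `unmatched_b` attributes (gene-name synonym
#' mismatches surface there rather than silently deflating overlaps).
#'
#' @param markersA,markersB [MarkerTable]s, already threshold-filtered.
#' @return integer matrix (subgroups of A x subgroups of B) with
#'   `unmatched_a`/`unmatched_b` attributes.
#' @export
overlapMatrix <- function(markersA, markersB) {
  .stopIfNot(nrow(markersA) > 0 && nrow(markersB) > 0,
             "empty marker table")
  sgA <- metadata(markersA)$subgroups
  sgB <- metadata(markersB)$subgroups
  gsA <- split(markersA$gene, factor(markersA$subgroup, levels = sgA))
  gsB <- split(markersB$gene, factor(markersB$subgroup, levels = sgB))
  M <- matrix(0L, length(sgA), length(sgB), dimnames = list(sgA, sgB))
  for (a in sgA) for (b in sgB)
    M[a, b] <- length(intersect(gsA[[a]], gsB[[b]]))
  attr(M, "unmatched_a") <- sum(!unique(markersA$gene) %in% markersB$gene)
  attr(M, "unmatched_b") <- sum(!unique(markersB$gene) %in% markersA$gene)
  M
}

#' Shared markers of a subgroup pair, with both enrichment levels
#'
#' Returns the genes marking both subgroup `a` (dataset A) and subgroup
#' `b` (dataset B) with the log2 enrichment of each side, sorted by the
#' smaller of the two enrichments, descending — the data behind a
#' cross-study enrichment scatter plot.
#'
#' @inheritParams overlapMatrix
#' @param a,b subgroup names in A and B.
#' @return data.frame (gene, log2fc_a, log2fc_b); empty with a warning
#'   when the pair shares no marker.
#' @export
pairedEnrichment <- function(markersA, markersB, a, b) {
  ta <- markersA[markersA$subgroup == a, , drop = FALSE]
  tb <- markersB[markersB$subgroup == b, , drop = FALSE]
  shared <- intersect(ta$gene, tb$gene)
  if (!length(shared)) {
    warning("subgroups '", a, "' and '", b, "' share no markers")
    return(data.frame(gene = character(), log2fc_a = numeric(),
                      log2fc_b = numeric()))
  }
  df <- data.frame(gene = shared,
                   log2fc_a = ta$log2fc[match(shared, ta$gene)],
                   log2fc_b = tb$log2fc[match(shared, tb$gene)],
                   stringsAsFactors = FALSE)
  df[order(-pmin(df$log2fc_a, df$log2fc_b)), , drop = FALSE]
}

#' Match score of a subgroup pair
#'
#' Additive specificity-weighted enrichment score over the shared markers:
#' `sum_g min(log2fc_a, log2fc_b) * (1 - max(spec_a, spec_b) + 1/Kbar)`
#' where spec is the marker-specificity fraction in each dataset and
#' `Kbar` the mean subgroup count of the two datasets. The score grows
#' with shared-marker count and enrichment and down-weights ubiquitous
#' markers; a fully specific marker carries weight 1. When either table
#' lacks enrichment values (figure-derived lists), the score degrades to
#' the shared-marker count.
#'
#' @param pe data.frame from [pairedEnrichment()].
#' @param specA,specB named specificity vectors (gene -> k/K) for the two
#'   datasets.
#' @param Kbar mean subgroup count of the two datasets.
#' @return numeric score >= 0.
#' @export
matchScore <- function(pe, specA, specB, Kbar) {
  if (!nrow(pe)) return(0)
  if (anyNA(pe$log2fc_a) || anyNA(pe$log2fc_b))
    return(nrow(pe))
  sa <- specA[pe$gene]; sb <- specB[pe$gene]
  sa[is.na(sa)] <- 1 / Kbar; sb[is.na(sb)] <- 1 / Kbar
  w <- 1 - pmax(sa, sb) + 1 / Kbar
  sum(pmin(pe$log2fc_a, pe$log2fc_b) * w)
}

#' Consensus correspondence between the subgroups of two datasets
#'
#' Computes all pairwise [matchScore()]s, declares reciprocal-best-hit
#' pairs, flags ties (runner-up within `tieBand` of the best, supporting
#' one-to-many correspondences), and optionally annotates pairs as
#' trajectory-discordant when exactly one member is a designated
#' developmental-root subgroup (annotated, never dropped). Named
#' subgroups can be excluded up front (e.g. a condition-specific subgroup
#' absent from the other study).
#'
#' @inheritParams overlapMatrix
#' @param tieBand runner-up scores >= `tieBand * best` are reported as tie
#'   partners (default 0.8).
#' @param excludeSubgroups character; subgroups dropped from either table
#'   before comparison.
#' @param trajectoryRoots optional list with elements `a` and `b`: root
#'   subgroup names per dataset.
#' @return A [CorrespondenceMap].
#' @export
consensusMap <- function(markersA, markersB, tieBand = 0.8,
                         excludeSubgroups = character(),
                         trajectoryRoots = NULL) {
  .stopIfNot(nrow(markersA) > 0 && nrow(markersB) > 0,
             "empty marker table")
  dropFrom <- function(m) {
    keep <- !(m$subgroup %in% excludeSubgroups)
    out <- MarkerTable(as.data.frame(m)[keep, , drop = FALSE],
                       subgroups = setdiff(metadata(m)$subgroups,
                                           excludeSubgroups))
    out
  }
  if (length(excludeSubgroups)) {
    markersA <- dropFrom(markersA)
    markersB <- dropFrom(markersB)
  }
  sgA <- metadata(markersA)$subgroups
  sgB <- metadata(markersB)$subgroups
  specA <- .specificityAll(markersA)
  specB <- .specificityAll(markersB)
  Kbar <- (length(sgA) + length(sgB)) / 2
  O <- overlapMatrix(markersA, markersB)
  S <- matrix(0, length(sgA), length(sgB), dimnames = list(sgA, sgB))
  for (a in sgA) for (b in sgB) {
    if (O[a, b] == 0) next
    pe <- suppressWarnings(pairedEnrichment(markersA, markersB, a, b))
    S[a, b] <- matchScore(pe, specA, specB, Kbar)
  }
  bestB <- apply(S, 1, function(r) colnames(S)[which.max(r)])
  bestA <- apply(S, 2, function(cl) rownames(S)[which.max(cl)])
  rows <- lapply(sgA, function(a) {
    b <- bestB[[a]]
    sc <- S[a, b]
    recip <- identical(bestA[[b]], a) && sc > 0
    others <- setdiff(sgB, b)
    ties <- others[S[a, others] >= tieBand * sc & S[a, others] > 0]
    data.frame(subgroup_a = a, subgroup_b = b, score = sc,
               n_shared = O[a, b], reciprocal_best = recip,
               tie_partners = paste(ties, collapse = ","),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  if (!is.null(trajectoryRoots)) {
    rootA <- pairs$subgroup_a %in% trajectoryRoots$a
    rootB <- pairs$subgroup_b %in% trajectoryRoots$b
    pairs$trajectory_discordant <- xor(rootA, rootB)
  }
  new("CorrespondenceMap", pairs = as(pairs, "DFrame"), scores = S,
      overlap = O)
}

#' Reciprocal-best-hit pairs of a CorrespondenceMap
#' @param map A [CorrespondenceMap].
#' @return data.frame of subgroup_a, subgroup_b restricted to reciprocal
#'   best hits.
#' @export
reciprocalBestHits <- function(map) {
  p <- as.data.frame(correspondencePairs(map))
  p[p$reciprocal_best, c("subgroup_a", "subgroup_b"), drop = FALSE]
}
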