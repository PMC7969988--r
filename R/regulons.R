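# Regulon activity: per-cell gene rankings with seeded tie-breaking, area
# under the recovery curve within the top fraction of each cell's ranking
# (AUCell-style), and one-vs-rest Mann-Whitney differential activity with
# the |z| > 2 selection rule.

#' Rank genes per cell
#'
#' Per cell, genes are ranked by decreasing expression. Ties — including
#' the bulk of undetected genes — are broken by a fixed seeded permutation
#' of gene order, so rankings (and downstream activity scores) are
#' reproducible; the seed is recorded in the result.
#'
#' @param x SingleCellExperiment with `logcounts`, or genes x cells
#'   matrix.
#' @param tieSeed seed of the tie-breaking permutation (default 1).
#' @return integer genes x cells matrix of ranks (1 = highest expression)
#'   with attributes `tieSeed` and `permutation`.
#' @export
rankGenesPerCell <- function(x, tieSeed = 1) {
  X <- .getLogcounts(x)
  G <- nrow(X)
  perm <- .withSeed(tieSeed, sample.int(G))
  ranks <- matrix(0L, G, ncol(X), dimnames = dimnames(X))
  for (j in seq_len(ncol(X))) {
    ord <- order(-X[, j], perm)
    ranks[ord, j] <- seq_len(G)
  }
  attr(ranks, "tieSeed") <- tieSeed
  attr(ranks, "permutation") <- perm
  ranks
}

#' AUCell-style regulon activity scores
#'
#' For each cell and regulon, the recovery curve counts regulon genes
#' among the top x ranked genes for x = 1..T, T = `ceiling(topFraction *
#' G)`. The activity score is the area under this step curve normalized by
#' its maximum possible value (all regulon genes at the very top), so
#' scores lie in [0, 1]. Regulon genes absent from the gene universe are
#' dropped with a warning; a regulon empty after filtering is an error.
#'
#' @param ranks genes x cells rank matrix from [rankGenesPerCell()], or an
#'   object accepted by it.
#' @param regulons named list of target-gene vectors (see [readGMT()]).
#' @param topFraction fraction of the ranking examined (default 0.05).
#' @param tieSeed used if `ranks` is not already a rank matrix.
#' @return A [RegulonActivity] (regulons x cells).
#' @export
aucellScore <- function(ranks, regulons, topFraction = 0.05, tieSeed = 1) {
  .stopIfNot(topFraction > 0 && topFraction < 1,
             "topFraction must lie in (0, 1)")
  .stopIfNot(length(regulons) > 0 && !is.null(names(regulons)),
             "regulons must be a non-empty named list")
  if (is.null(attr(ranks, "tieSeed")))
    ranks <- rankGenesPerCell(ranks, tieSeed = tieSeed)
  G <- nrow(ranks)
  Tn <- ceiling(topFraction * G)
  auc <- matrix(NA_real_, length(regulons), ncol(ranks),
                dimnames = list(names(regulons), colnames(ranks)))
  for (rg in names(regulons)) {
    targets <- intersect(regulons[[rg]], rownames(ranks))
    dropped <- setdiff(regulons[[rg]], targets)
    if (length(dropped))
      warning("regulon '", rg, "': ", length(dropped),
              " target(s) absent from the gene universe, dropped")
    if (!length(targets))
      stop("regulon '", rg, "' is empty after filtering")
    M <- ranks[targets, , drop = FALSE]
    # gene at rank p contributes (T - p + 1) steps to the raw area
    contrib <- pmax(Tn - M + 1, 0)
    maxraw <- sum(Tn - seq_len(min(length(targets), Tn)) + 1)
    auc[rg, ] <- colSums(contrib) / maxraw
  }
  se <- SummarizedExperiment(assays = list(auc = auc))
  metadata(se)$topFraction <- topFraction
  metadata(se)$threshold <- Tn
  metadata(se)$tieSeed <- attr(ranks, "tieSeed")
  new("RegulonActivity", se)
}

#' Differential regulon activity per cluster
#'
#' Per regulon and cluster, a one-vs-rest two-sided Mann-Whitney test on
#' the AUC scores with tie-corrected normal approximation; the z-score
#' `(U - n1*n2/2) / sigma_tie` is signed so that positive means higher
#' activity in the cluster. Regulons with z above `zThreshold` or below
#' `-zThreshold` are flagged selected. An exact enumeration p is reported
#' additionally when both sides have at most 8 cells. Rows of the z matrix
#' are ordered by hierarchical clustering (Euclidean distance, complete
#' linkage) for heatmap-style export.
#'
#' @param activity [RegulonActivity] from [aucellScore()], or a regulons x
#'   cells score matrix.
#' @param labels cluster labels per cell (defaults to any `subgroup`
#'   colData of `activity`).
#' @param zThreshold selection threshold (default 2: selected iff z > 2 or
#'   z < -2).
#' @return [S4Vectors::DataFrame] (regulon, cluster, U, p, z, selected,
#'   and p_exact where computed) with `metadata()`: `zMatrix` (regulon x
#'   cluster), `rowOrder`, `linkage`, `zThreshold`.
#' @export
differentialActivity <- function(activity, labels = NULL, zThreshold = 2) {
  A <- if (is(activity, "SummarizedExperiment"))
    as.matrix(assay(activity, "auc")) else as.matrix(activity)
  labels <- .getLabels(activity, labels)
  clusters <- sort(unique(labels))
  .stopIfNot(all(table(labels) >= 3), "every cluster needs at least 3 cells")
  .stopIfNot(length(clusters) >= 2, "need at least 2 clusters")
  RK <- apply(A, 1, rank)               # cells x regulons
  tie <- apply(RK, 2, .tieTerm)
  res <- list()
  Z <- matrix(0, nrow(A), length(clusters),
              dimnames = list(rownames(A), clusters))
  for (cl in clusters) {
    inIdx <- which(labels == cl)
    n1 <- length(inIdx); n2 <- length(labels) - n1
    U <- colSums(RK[inIdx, , drop = FALSE]) - n1 * (n1 + 1) / 2
    nz <- .ranksumNormal(U, n1, n2, tie, correct = FALSE)
    Z[, cl] <- nz$z
    df <- data.frame(regulon = rownames(A), cluster = cl, U = unname(U),
                     p = unname(nz$p), z = unname(nz$z),
                     selected = abs(unname(nz$z)) > zThreshold,
                     stringsAsFactors = FALSE)
    if (n1 <= 8 && n2 <= 8)
      df$p_exact <- vapply(rownames(A), function(rg)
        .ranksumExact(A[rg, inIdx], A[rg, -inIdx])$p, numeric(1))
    res[[cl]] <- df
  }
  out <- as(do.call(rbind, res), "DFrame")
  rownames(out) <- NULL
  rowOrder <- seq_len(nrow(Z))
  if (nrow(Z) >= 3)
    rowOrder <- hclust(dist(Z), method = "complete")$order
  metadata(out) <- list(zMatrix = Z, rowOrder = rowOrder,
                        linkage = "complete", zThreshold = zThreshold)
  out
}

#' Regulons selected for a cluster
#' @param da result of [differentialActivity()].
#' @param cluster cluster name.
#' @return data.frame of selected regulons for that cluster, by |z|.
#' @export
selectedRegulons <- function(da, cluster) {
  df <- as.data.frame(da)
  df <- df[df$cluster == cluster & df$selected, , drop = FALSE]
  df[order(-abs(df$z)), , drop = FALSE]
}
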