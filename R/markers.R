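# Marker detection: log-normalization, one-vs-rest Wilcoxon rank-sum per
# gene, log2 enrichment on the depth-normalized scale, Bonferroni
# adjustment over the genes actually tested, and the retention thresholds
# log2fc > 0.25, adjusted p < 0.01.

#' Log-normalize a count matrix
#'
#' Per cell, counts are scaled to a common depth and natural-log
#' transformed: `ln(1 + count * scaleFactor / cellTotal)`. Cells with zero
#' total stay all-zero with a warning. A zero count maps to exactly 0.
#'
#' @param x SingleCellExperiment with a `counts` assay, or genes x cells
#'   count matrix.
#' @param scaleFactor common depth, default 10000.
#' @return For an SCE input, the SCE with a `logcounts` assay added;
#'   otherwise the genes x cells log-normalized matrix.
#' @export
logNormalize <- function(x, scaleFactor = 1e4) {
  .stopIfNot(scaleFactor > 0, "scaleFactor must be positive")
  m <- if (is(x, "SummarizedExperiment")) as.matrix(assay(x, "counts")) else
    as.matrix(x)
  tot <- colSums(m)
  if (any(tot == 0))
    warning(sum(tot == 0), " cell(s) with zero total count left all-zero")
  sf <- ifelse(tot > 0, scaleFactor / tot, 0)
  norm <- log1p(sweep(m, 2, sf, `*`))
  if (is(x, "SummarizedExperiment")) {
    assay(x, "logcounts") <- norm
    x
  } else norm
}

# Shared per-dataset rank structures: midranks of every gene across all
# cells (one-vs-rest reuses one ranking for every subgroup) plus tie terms.
.rankStructures <- function(X) {
  RK <- apply(X, 1, rank)           # cells x genes
  tie <- apply(RK, 2, .tieTerm)
  list(ranks = RK, tie = tie)
}

# Vectorized one-vs-rest marker statistics for one subgroup.
.markerStats <- function(X, expm, inIdx, rs) {
  n1 <- length(inIdx); n2 <- ncol(X) - n1
  pctIn <- rowMeans(X[, inIdx, drop = FALSE] > 0)
  pctOut <- rowMeans(X[, -inIdx, drop = FALSE] > 0)
  meanIn <- rowMeans(expm[, inIdx, drop = FALSE])
  meanOut <- rowMeans(expm[, -inIdx, drop = FALSE])
  log2fc <- log2((meanIn + 1) / (meanOut + 1))
  R1 <- colSums(rs$ranks[inIdx, , drop = FALSE])
  U <- R1 - n1 * (n1 + 1) / 2
  nz <- .ranksumNormal(U, n1, n2, rs$tie)
  list(gene = rownames(X), U = U, z = nz$z, p = nz$p, log2fc = log2fc,
       pct_in = pctIn, pct_out = pctOut, n1 = n1, n2 = n2)
}

#' Rank-sum marker test for a single gene
#'
#' Two-sided Wilcoxon rank-sum of one subgroup versus all other cells,
#' with midranks and tie-corrected normal approximation; when both groups
#' have at most `exactMax` cells the p-value is computed by exact
#' enumeration over all rank assignments. The log2 enrichment is computed
#' on depth-normalized (pre-log, `expm1`) means with pseudocount 1, and
#' detection fractions are reported.
#'
#' @param x SingleCellExperiment with `logcounts`, or a genes x cells
#'   log-normalized matrix.
#' @param subgroup subgroup to contrast against the rest.
#' @param gene gene id (rowname).
#' @param labels cluster labels (defaults to `colData(x)$subgroup`).
#' @param exactMax exact-enumeration cutoff per group size (default 8).
#' @return One-row [S4Vectors::DataFrame] with gene, subgroup, log2fc, U,
#'   p, pct_in, pct_out.
#' @export
markerTest <- function(x, subgroup, gene, labels = NULL, exactMax = 8) {
  X <- .getLogcounts(x)
  labels <- .getLabels(x, labels)
  .stopIfNot(gene %in% rownames(X), "unknown gene: ", gene)
  inIdx <- which(labels == subgroup)
  n1 <- length(inIdx); n2 <- length(labels) - n1
  .stopIfNot(n1 >= 3 && n2 >= 3,
             "need at least 3 cells in the subgroup and in the rest")
  v <- X[gene, ]
  xin <- v[inIdx]; xout <- v[-inIdx]
  ein <- expm1(xin); eout <- expm1(xout)
  log2fc <- log2((mean(ein) + 1) / (mean(eout) + 1))
  if (n1 <= exactMax && n2 <= exactMax) {
    ex <- .ranksumExact(xin, xout)
    U <- ex$U; p <- ex$p
  } else {
    r <- rank(v)
    U <- sum(r[inIdx]) - n1 * (n1 + 1) / 2
    nz <- .ranksumNormal(U, n1, n2, .tieTerm(r))
    p <- nz$p
  }
  DataFrame(gene = gene, subgroup = subgroup, log2fc = log2fc, U = U,
            p = p, pct_in = mean(xin > 0), pct_out = mean(xout > 0))
}

#' Detect markers of one subgroup
#'
#' Tests every gene passing the detection pre-filter (expressed in at
#' least `minPct` of the subgroup or of the rest) with the one-vs-rest
#' rank-sum test, Bonferroni-adjusts over the genes actually tested, and
#' retains genes with `log2fc > log2fcMin` and `p_adj < pAdjMax`, sorted
#' by descending log2fc.
#'
#' @inheritParams markerTest
#' @param log2fcMin minimum log2 enrichment, exclusive (default 0.25).
#' @param pAdjMax maximum Bonferroni-adjusted p, exclusive (default 0.01).
#' @param minPct detection pre-filter (default 0.1).
#' @return A [MarkerTable].
#' @export
findMarkers <- function(x, subgroup, labels = NULL, log2fcMin = 0.25,
                        pAdjMax = 0.01, minPct = 0.1) {
  X <- .getLogcounts(x)
  labels <- .getLabels(x, labels)
  rs <- .rankStructures(X)
  expm <- expm1(X)
  res <- .findMarkersOne(X, expm, labels, subgroup, rs, log2fcMin, pAdjMax,
                         minPct)
  MarkerTable(res, subgroups = sort(unique(labels)))
}

.findMarkersOne <- function(X, expm, labels, subgroup, rs, log2fcMin,
                            pAdjMax, minPct) {
  inIdx <- which(labels == subgroup)
  .stopIfNot(length(inIdx) > 0, "empty subgroup: ", subgroup)
  .stopIfNot(length(inIdx) >= 3 && length(labels) - length(inIdx) >= 3,
             "need at least 3 cells per side for subgroup ", subgroup)
  st <- .markerStats(X, expm, inIdx, rs)
  tested <- st$pct_in >= minPct | st$pct_out >= minPct
  nTested <- sum(tested)
  pAdj <- pmin(1, st$p * nTested)
  keep <- tested & st$log2fc > log2fcMin & pAdj < pAdjMax
  ord <- order(-st$log2fc[keep])
  data.frame(gene = st$gene[keep][ord],
             subgroup = rep(subgroup, sum(keep)),
             log2fc = st$log2fc[keep][ord], p = st$p[keep][ord],
             p_adj = pAdj[keep][ord], pct_in = st$pct_in[keep][ord],
             pct_out = st$pct_out[keep][ord], stringsAsFactors = FALSE)
}

#' Detect markers of every subgroup
#'
#' Runs [findMarkers()] for each subgroup, sharing the per-gene ranking
#' across the one-vs-rest contrasts. Subgroups retaining no markers are
#' still part of the table's subgroup universe (`metadata()$subgroups`).
#'
#' @inheritParams findMarkers
#' @return A [MarkerTable] covering all subgroups.
#' @export
findAllMarkers <- function(x, labels = NULL, log2fcMin = 0.25,
                           pAdjMax = 0.01, minPct = 0.1) {
  X <- .getLogcounts(x)
  labels <- .getLabels(x, labels)
  rs <- .rankStructures(X)
  expm <- expm1(X)
  subgroups <- sort(unique(labels))
  parts <- lapply(subgroups, function(sg)
    .findMarkersOne(X, expm, labels, sg, rs, log2fcMin, pAdjMax, minPct))
  MarkerTable(do.call(rbind, parts), subgroups = subgroups)
}

#' Marker specificity of a gene
#'
#' Fraction k/K where k is the number of subgroups listing the gene as a
#' retained marker and K the total number of subgroups of the dataset.
#' Lower means more specific; a gene that is never a marker returns 0 with
#' a warning.
#'
#' @param markers [MarkerTable] covering all subgroups of one dataset.
#' @param gene gene id.
#' @return numeric in [0, 1].
#' @export
markerSpecificity <- function(markers, gene) {
  K <- length(metadata(markers)$subgroups)
  .stopIfNot(K > 0, "marker table carries no subgroup universe")
  k <- length(unique(markers$subgroup[markers$gene == gene]))
  if (k == 0) {
    warning("gene '", gene, "' is not a marker of any subgroup")
    return(0)
  }
  k / K
}

# Specificity for every marker gene of a table at once (named vector).
.specificityAll <- function(markers) {
  K <- length(metadata(markers)$subgroups)
  tab <- table(unique(data.frame(gene = markers$gene,
                                 subgroup = markers$subgroup))$gene)
  setNames(as.numeric(tab) / K, names(tab))
}
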