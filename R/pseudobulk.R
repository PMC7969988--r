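# Pseudo-bulk ("pseudo-transcriptome") construction, Pearson-correlation
# annotation of query subgroups against a reference atlas, canonical-marker
# identification of hemocyte clusters in tissue datasets, and extraction of
# query-specific signatures.

#' Default canonical hemocyte markers
#'
#' Union of the canonical pan-hemocyte markers used to pick out hemocyte
#' clusters in embryo, eye-disc and brain datasets: Srp, Hml, Pxn, NimC1,
#' He, Crq, Sn.
#' @return character vector.
#' @export
hemocyteMarkers <- function() c("Srp", "Hml", "Pxn", "NimC1", "He", "Crq", "Sn")

#' Per-subgroup mean expression profiles
#'
#' For each subgroup, the arithmetic mean over member cells of
#' depth-normalized (pre-log, `expm1(logcounts)`) expression — the
#' "pseudo-transcriptome" of the subgroup. Per-gene detection fractions
#' per subgroup are kept alongside for signature extraction.
#'
#' @param x SingleCellExperiment with `logcounts`, or genes x cells
#'   log-normalized matrix.
#' @param labels cluster labels (defaults to `colData(x)$subgroup`).
#' @return A [PseudoTranscriptome] (genes x subgroups).
#' @export
pseudoTranscriptome <- function(x, labels = NULL) {
  X <- .getLogcounts(x)
  labels <- .getLabels(x, labels)
  expm <- expm1(X)
  subgroups <- sort(unique(labels))
  avg <- vapply(subgroups, function(sg)
    rowMeans(expm[, labels == sg, drop = FALSE]), numeric(nrow(X)))
  det <- vapply(subgroups, function(sg)
    rowMeans(X[, labels == sg, drop = FALSE] > 0), numeric(nrow(X)))
  dimnames(avg) <- dimnames(det) <- list(rownames(X), subgroups)
  out <- SummarizedExperiment(
    assays = list(avgExpr = avg),
    colData = DataFrame(nCells = as.integer(table(factor(labels,
                                                         subgroups)))))
  colnames(out) <- subgroups
  metadata(out)$detection <- det
  new("PseudoTranscriptome", out)
}

#' Pearson correlation between pseudo-transcriptomes
#'
#' Correlates every query subgroup with every reference subgroup on the
#' shared-gene intersection (or a supplied gene list, e.g. the reference's
#' variable genes), after `log1p` re-transform of both mean-expression
#' profiles. The gene policy and the number of genes used are recorded as
#' attributes of the returned matrix.
#'
#' @param query,ref [PseudoTranscriptome]s.
#' @param genePolicy `"intersection"` (all shared genes) or `"genes"`
#'   (restrict to `genes`).
#' @param genes gene list for `genePolicy = "genes"`.
#' @return query-subgroup x reference-subgroup matrix of Pearson r, with
#'   attributes `n_genes` and `gene_policy`. Zero-variance profiles give
#'   `NA` entries with a warning.
#' @export
correlatePseudo <- function(query, ref,
                            genePolicy = c("intersection", "genes"),
                            genes = NULL) {
  genePolicy <- match.arg(genePolicy)
  shared <- intersect(rownames(query), rownames(ref))
  if (genePolicy == "genes") {
    .stopIfNot(!is.null(genes), "genePolicy 'genes' needs a gene list")
    shared <- intersect(shared, genes)
  }
  .stopIfNot(length(shared) >= 3,
             "fewer than 3 shared genes between query and reference")
  Q <- log1p(assay(query, "avgExpr")[shared, , drop = FALSE])
  R <- log1p(assay(ref, "avgExpr")[shared, , drop = FALSE])
  zvQ <- apply(Q, 2, function(v) var(v) == 0)
  zvR <- apply(R, 2, function(v) var(v) == 0)
  if (any(zvQ) || any(zvR))
    warning("zero-variance pseudo-transcriptome column(s); r reported as NA")
  M <- suppressWarnings(cor(Q, R))
  M[zvQ, ] <- NA_real_
  M[, zvR] <- NA_real_
  attr(M, "n_genes") <- length(shared)
  attr(M, "gene_policy") <- genePolicy
  M
}

#' Rank reference matches per query subgroup
#'
#' Per query subgroup, reference subgroups sorted by decreasing r; the top
#' `topK` are returned with the margin to the next-ranked reference. Exact
#' ties are broken lexicographically on the reference name and flagged.
#'
#' @param corMat matrix from [correlatePseudo()].
#' @param topK matches to report per query subgroup (default 3).
#' @return data.frame (query, rank, reference, r, margin, tie).
#' @export
annotateBestMatch <- function(corMat, topK = 3) {
  rows <- lapply(rownames(corMat), function(q) {
    r <- setNames(corMat[q, ], colnames(corMat))
    ord <- order(-r, names(r))
    k <- min(topK, length(ord))
    sel <- ord[seq_len(k)]
    nxt <- c(r[ord][-1], NA_real_)[seq_len(k)]
    tie <- vapply(sel, function(i) sum(r == r[i], na.rm = TRUE) > 1,
                  logical(1))
    data.frame(query = q, rank = seq_len(k), reference = names(r)[sel],
               r = unname(r[sel]), margin = unname(r[sel] - nxt),
               tie = unname(tie), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Identify hemocyte clusters in a tissue dataset by canonical markers
#'
#' Scores each cluster of a tissue pseudo-transcriptome by the mean, over
#' canonical hemocyte markers, of the cluster's expression quantile for
#' that marker across clusters (quantile 1 = highest-expressing cluster).
#' Clusters with score >= `scoreMin` and at least half the markers at
#' their per-gene maximum are called hemocytes. The full evidence table is
#' always returned.
#'
#' @param pt [PseudoTranscriptome] of the tissue's clusters.
#' @param markers canonical marker genes (default [hemocyteMarkers()]).
#' @param scoreMin minimum mean quantile score (default 0.9).
#' @return list with `clusters` (character, possibly empty with a
#'   warning) and `evidence` (data.frame: cluster, score, n_at_max,
#'   n_markers_used).
#' @export
identifyHemocyteCluster <- function(pt, markers = hemocyteMarkers(),
                                    scoreMin = 0.9) {
  .stopIfNot(length(markers) > 0, "marker list is empty")
  use <- intersect(markers, rownames(pt))
  E <- assay(pt, "avgExpr")[use, , drop = FALSE]
  K <- ncol(E)
  if (!length(use) || all(E == 0)) {
    warning("no canonical marker expressed in any cluster")
    return(list(clusters = character(),
                evidence = data.frame(cluster = colnames(pt),
                                      score = NA_real_, n_at_max = 0L,
                                      n_markers_used = length(use))))
  }
  qt <- t(apply(E, 1, function(v)
    if (K > 1) (rank(v, ties.method = "average") - 1) / (K - 1) else 1))
  atMax <- t(apply(E, 1, function(v) v == max(v) & max(v) > 0))
  score <- colMeans(qt)
  nAtMax <- colSums(atMax)
  pass <- score >= scoreMin & nAtMax >= length(use) / 2
  ev <- data.frame(cluster = colnames(E), score = unname(score),
                   n_at_max = as.integer(nAtMax),
                   n_markers_used = length(use), stringsAsFactors = FALSE)
  ev <- ev[order(-ev$score), , drop = FALSE]
  if (!any(pass)) warning("no cluster passes the hemocyte-marker rule")
  list(clusters = colnames(E)[pass], evidence = ev)
}

#' Query-specific signature genes
#'
#' Genes expressed in the query pseudo-transcriptome at least `foldMin`
#' times the maximum over all reference subgroups (on the depth-normalized
#' scale, pseudocount 1, boundary inclusive) and detected in at least
#' `detectMin` of query cells, sorted by fold ratio.
#'
#' @param query single-subgroup [PseudoTranscriptome] (or a named column
#'   chosen via `queryColumn`).
#' @param ref reference [PseudoTranscriptome] of all subgroups.
#' @param queryColumn column of `query` to use (default the first).
#' @param foldMin fold threshold (default 2).
#' @param detectMin minimum query detection fraction (default 0.5).
#' @return data.frame (gene, fold, detection), possibly empty.
#' @export
specificSignature <- function(query, ref, queryColumn = 1, foldMin = 2,
                              detectMin = 0.5) {
  shared <- intersect(rownames(query), rownames(ref))
  q <- assay(query, "avgExpr")[shared, queryColumn]
  det <- metadata(query)$detection
  .stopIfNot(!is.null(det), "query carries no detection fractions")
  det <- det[shared, queryColumn]
  refMax <- apply(assay(ref, "avgExpr")[shared, , drop = FALSE], 1, max)
  fold <- (q + 1) / (refMax + 1)
  keep <- fold >= foldMin & det >= detectMin
  out <- data.frame(gene = shared[keep], fold = unname(fold[keep]),
                    detection = unname(det[keep]), stringsAsFactors = FALSE)
  out[order(-out$fold), , drop = FALSE]
}

#' Mean expression and detection per subgroup for selected genes
#'
#' The data behind a marker dot plot: per subgroup, the mean
#' depth-normalized expression and the fraction of cells expressing each
#' gene.
#'
#' @inheritParams pseudoTranscriptome
#' @param genes genes to report (absent genes are dropped).
#' @return data.frame (gene, subgroup, mean_expr, pct_expr).
#' @export
markerDotData <- function(x, genes, labels = NULL) {
  pt <- pseudoTranscriptome(x, labels)
  use <- intersect(genes, rownames(pt))
  avg <- assay(pt, "avgExpr")[use, , drop = FALSE]
  det <- metadata(pt)$detection[use, , drop = FALSE]
  data.frame(gene = rep(use, times = ncol(avg)),
             subgroup = rep(colnames(avg), each = length(use)),
             mean_expr = as.vector(avg), pct_expr = as.vector(det),
             stringsAsFactors = FALSE)
}
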