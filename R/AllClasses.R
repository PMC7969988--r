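#' MarkerTable: per-subgroup enriched genes
#'
#' A [S4Vectors::DataFrame]-derived table of marker genes with one row per
#' (gene, subgroup) pair and columns `gene`, `subgroup`, `log2fc` (log2
#' enrichment of the subgroup over the rest), `p` (raw two-sided rank-sum
#' p-value), `p_adj` (Bonferroni-adjusted, capped at 1), `pct_in` and
#' `pct_out` (detection fractions inside/outside the subgroup).
#'
#' The complete subgroup universe of the dataset (including subgroups that
#' retained no markers) is kept in `metadata(x)$subgroups`; marker
#' specificity is computed against it.
#'
#' @aliases MarkerTable-class
#' @seealso [findMarkers()], [markerSpecificity()], [writeMarkerTable()]
#' @export
setClass("MarkerTable", contains = "DFrame")

.validMarkerTable <- function(object) {
  need <- c("gene", "subgroup", "log2fc", "p", "p_adj", "pct_in", "pct_out")
  msg <- character()
  if (!all(need %in% colnames(object)))
    msg <- c(msg, paste("missing columns:",
                        paste(setdiff(need, colnames(object)), collapse = ", ")))
  else {
    if (nrow(object)) {
      # NA statistics are allowed (figure-derived lists carry genes only)
      if (any(is.infinite(object$log2fc) | is.nan(object$log2fc)))
        msg <- c(msg, "log2fc must be finite")
      if (any(object$pct_in < 0 | object$pct_in > 1, na.rm = TRUE) ||
          any(object$pct_out < 0 | object$pct_out > 1, na.rm = TRUE))
        msg <- c(msg, "pct_in/pct_out must lie in [0, 1]")
      if (any(object$p < 0 | object$p > 1, na.rm = TRUE))
        msg <- c(msg, "p must lie in [0, 1]")
      if (any(object$p > object$p_adj + 1e-12, na.rm = TRUE))
        msg <- c(msg, "p must not exceed p_adj")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("MarkerTable", .validMarkerTable)

#' Construct a MarkerTable
#'
#' @param df data.frame or DataFrame with the required marker columns.
#' @param subgroups character vector of all subgroups of the dataset the
#'   table was computed from; defaults to the subgroups present in `df`.
#' @return A [MarkerTable] object.
#' @export
MarkerTable <- function(df, subgroups = NULL) {
  df <- as(as.data.frame(df), "DFrame")
  out <- new("MarkerTable", df)
  metadata(out)$subgroups <-
    if (is.null(subgroups)) unique(as.character(df$subgroup)) else
      as.character(subgroups)
  validObject(out)
  out
}

#' CorrespondenceMap: scored subgroup matching between two datasets
#'
#' Holds the full pairwise score matrix, the shared-marker overlap counts,
#' and a per-subgroup table of best matches with reciprocal-best-hit flags
#' and tie partners (runner-up matches scoring within the tie band of the
#' best).
#'
#' @slot pairs DataFrame with columns `subgroup_a`, `subgroup_b`, `score`,
#'   `n_shared`, `reciprocal_best`, `tie_partners` (comma-separated, may be
#'   empty) and optionally `trajectory_discordant`.
#' @slot scores numeric matrix, subgroups of A x subgroups of B.
#' @slot overlap integer matrix of shared retained-marker counts, same
#'   dimnames as `scores`.
#'
#' @aliases CorrespondenceMap-class
#' @seealso [consensusMap()], [overlapMatrix()]
#' @export
setClass("CorrespondenceMap",
         slots = c(pairs = "DFrame", scores = "matrix", overlap = "matrix"))

setValidity("CorrespondenceMap", function(object) {
  msg <- character()
  if (!identical(dim(object@scores), dim(object@overlap)))
    msg <- c(msg, "scores and overlap dimensions differ")
  if (any(object@scores < -1e-9))
    msg <- c(msg, "scores must be non-negative")
  if (any(object@overlap < 0) || any(object@overlap != round(object@overlap)))
    msg <- c(msg, "overlap entries must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' PseudoTranscriptome: per-subgroup mean expression profiles
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one column per
#' subgroup and a single assay `avgExpr` holding, per gene, the arithmetic
#' mean of depth-normalized (pre-log, `expm1(logcounts)`) expression over
#' the member cells. Column metadata records `nCells` per subgroup and,
#' when available, per-gene detection fractions are kept in
#' `metadata(x)$detection` (gene x subgroup matrix).
#'
#' @aliases PseudoTranscriptome-class
#' @seealso [pseudoTranscriptome()], [correlatePseudo()]
#' @export
setClass("PseudoTranscriptome", contains = "SummarizedExperiment")

setValidity("PseudoTranscriptome", function(object) {
  msg <- character()
  if (!"avgExpr" %in% assayNames(object))
    msg <- c(msg, "assay 'avgExpr' required")
  else if (any(assay(object, "avgExpr") < 0))
    msg <- c(msg, "avgExpr entries must be non-negative")
  if (!"nCells" %in% names(colData(object)))
    msg <- c(msg, "colData column 'nCells' required")
  if (length(msg)) msg else TRUE
})

#' RegulonActivity: AUC scores of regulons per cell
#'
#' A [SummarizedExperiment::SummarizedExperiment] with regulons as rows,
#' cells as columns and a single assay `auc` of area-under-recovery-curve
#' scores in [0, 1]. `metadata()` records the `topFraction` of the per-cell
#' ranking used, the resulting rank `threshold`, and the `tieSeed` of the
#' seeded permutation that broke expression ties.
#'
#' @aliases RegulonActivity-class
#' @seealso [aucellScore()], [differentialActivity()]
#' @export
setClass("RegulonActivity", contains = "SummarizedExperiment")

setValidity("RegulonActivity", function(object) {
  msg <- character()
  if (!"auc" %in% assayNames(object))
    msg <- c(msg, "assay 'auc' required")
  else {
    a <- assay(object, "auc")
    if (any(a < -1e-12) || any(a > 1 + 1e-12))
      msg <- c(msg, "auc scores must lie in [0, 1]")
  }
  tf <- metadata(object)$topFraction
  if (is.null(tf) || tf <= 0 || tf >= 1)
    msg <- c(msg, "metadata topFraction must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})
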