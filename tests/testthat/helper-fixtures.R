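# Shared fixture builders: everything is generated in code at test time.

suppressPackageStartupMessages({
  library(S4Vectors)
  library(SummarizedExperiment)
  library(SingleCellExperiment)
})

# Tiny deterministic genes x cells count matrix.
fixtureCounts <- function(nGenes = 6, nCells = 8, seed = 1, lambda = 3) {
  set.seed(seed)
  m <- matrix(rpois(nGenes * nCells, lambda), nGenes, nCells,
              dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                              sprintf("c%02d", seq_len(nCells))))
  m
}

fixtureSCE <- function(nGenes = 6, nCells = 8, seed = 1, labels = NULL) {
  m <- fixtureCounts(nGenes, nCells, seed)
  sce <- SingleCellExperiment(assays = list(counts = m))
  if (!is.null(labels)) colData(sce)$subgroup <- labels
  sce
}

# Equal-proportion four-subgroup config for fast recovery tests.
quadConfig <- function(nCells = 600, nGenes = 300, seed = 1, ...) {
  studyConfig(nCells = nCells, nGenes = nGenes,
              proportions = setNames(rep(0.25, 4), paste0("sg", 1:4)),
              seed = seed, ...)
}

# Hand-built MarkerTable from parallel vectors.
mkTable <- function(gene, subgroup, log2fc = 1, subgroups = NULL) {
  n <- length(gene)
  MarkerTable(data.frame(
    gene = gene, subgroup = subgroup,
    log2fc = rep_len(log2fc, n), p = rep(1e-6, n), p_adj = rep(1e-4, n),
    pct_in = rep(0.9, n), pct_out = rep(0.05, n)), subgroups = subgroups)
}

# Independent brute-force rank-sum oracle: U from pairwise comparisons,
# exact two-sided p by subset enumeration over pooled values.
bruteRankSum <- function(x, y) {
  U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pooled <- c(x, y)
  n1 <- length(x); n2 <- length(y)
  mu <- n1 * n2 / 2
  sets <- combn(length(pooled), n1)
  Uall <- apply(sets, 2, function(ix) {
    xx <- pooled[ix]; yy <- pooled[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  list(U = U, p = mean(abs(Uall - mu) >= abs(U - mu) - 1e-9))
}

# Independent AUCell oracle: literal step-curve summation.
bruteAUC <- function(rankVec, targets, topFraction) {
  G <- length(rankVec)
  Tn <- ceiling(topFraction * G)
  hits <- vapply(seq_len(Tn), function(x) sum(rankVec[targets] <= x),
                 numeric(1))
  best <- vapply(seq_len(Tn), function(x) min(x, length(targets)),
                 numeric(1))
  sum(hits) / sum(best)
}

# Build a PseudoTranscriptome directly from an avgExpr matrix.
ptFrom <- function(avg, nCells = rep(10L, ncol(avg)), detection = NULL) {
  se <- SummarizedExperiment(assays = list(avgExpr = avg),
                             colData = DataFrame(nCells = nCells))
  colnames(se) <- colnames(avg)
  if (is.null(detection))
    detection <- matrix(1, nrow(avg), ncol(avg), dimnames = dimnames(avg))
  S4Vectors::metadata(se)$detection <- detection
  new("PseudoTranscriptome", se)
}
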