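# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Sum of t^3 - t over tie groups of a rank (or value) vector.
.tieTerm <- function(r) {
  tt <- rle(sort(r))$lengths
  sum(tt^3 - tt)
}

# Normal approximation to the two-sided rank-sum p, tie-corrected.
# U, tieterm may be vectors (one entry per gene/regulon).
.ranksumNormal <- function(U, n1, n2, tieterm, correct = TRUE) {
  n <- n1 + n2
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tieterm / (n * (n - 1)))
  sigma <- sqrt(pmax(sigma2, 0))
  d <- U - mu
  dc <- if (correct) d - sign(d) * 0.5 else d
  z <- ifelse(sigma > 0, dc / sigma, 0)
  p <- pmin(1, 2 * pnorm(-abs(z)))
  # uncorrected z is what downstream selection rules use
  zraw <- ifelse(sigma > 0, d / sigma, 0)
  list(z = zraw, p = p)
}

# Exact two-sided rank-sum p by enumeration of all C(n1+n2, n1) rank
# assignments of the pooled midranks; ties handled by construction.
.ranksumExact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  combs <- combn(n1 + n2, n1)
  R1 <- colSums(matrix(r[combs], nrow = n1))
  Uall <- R1 - n1 * (n1 + 1) / 2
  p <- mean(abs(Uall - mu) >= abs(U - mu) - 1e-9)
  list(U = U, p = p)
}

# Extract a genes x cells matrix of log-normalized expression.
.getLogcounts <- function(x) {
  if (is(x, "SingleCellExperiment") || is(x, "SummarizedExperiment")) {
    if (!"logcounts" %in% assayNames(x))
      stop("no 'logcounts' assay; run logNormalize() first")
    as.matrix(assay(x, "logcounts"))
  } else {
    as.matrix(x)
  }
}

# Resolve cluster labels for an SCE (colData column 'subgroup') or an
# explicit named/unnamed label vector aligned with the columns of x.
.getLabels <- function(x, labels = NULL) {
  if (is.null(labels)) {
    if (is(x, "SummarizedExperiment") && "subgroup" %in% names(colData(x)))
      labels <- as.character(colData(x)$subgroup)
    else
      stop("labels not given and no 'subgroup' column in colData")
  }
  labels <- as.character(labels)
  nc <- if (is(x, "SummarizedExperiment")) ncol(x) else ncol(as.matrix(x))
  if (length(labels) != nc)
    stop("length of labels (", length(labels),
         ") does not match number of cells (", nc, ")")
  labels
}

.stopIfNot <- function(cond, ...) if (!cond) stop(..., call. = FALSE)
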