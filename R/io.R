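# Readers and writers for on-disk formats: matrix-market triplets with
# features/barcodes companions, dense TSV count dumps, label tables, GMT
# regulon files, and marker tables.

#' Read a count matrix
#'
#' Reads either a matrix-market triplet file with companion one-column
#' features (gene) and barcodes (cell) files, or a dense TSV whose header
#' row names the genes and whose first column holds cell identifiers.
#' Orientation is auto-detected from the companion-file lengths (or the TSV
#' shape contract) and normalized so the returned object is always genes x
#' cells.
#'
#' @param path path to the `.mtx` triplet file or a dense `.tsv`.
#' @param features,barcodes companion file paths for the matrix-market
#'   form; default to `features.tsv` / `barcodes.tsv` next to `path`.
#' @return A [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay of non-negative integers, gene ids as rownames and cell ids as
#'   colnames.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' m <- matrix(rpois(6, 2), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
#' writeCounts(m, file.path(dir, "counts.tsv"))
#' sce <- readCounts(file.path(dir, "counts.tsv"))
#' @export
readCounts <- function(path,
                       features = file.path(dirname(path), "features.tsv"),
                       barcodes = file.path(dirname(path), "barcodes.tsv")) {
  .stopIfNot(file.exists(path), "count file not found: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as(readMM(path), "CsparseMatrix")
    .stopIfNot(file.exists(features), "features file not found: ", features)
    .stopIfNot(file.exists(barcodes), "barcodes file not found: ", barcodes)
    genes <- readLines(features)
    cells <- readLines(barcodes)
    genes <- genes[nzchar(genes)]
    cells <- cells[nzchar(cells)]
    if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      # genes x cells as written
    } else if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
      m <- Matrix::t(m)
    } else {
      bad <- if (length(genes) %in% dim(m)) barcodes else features
      stop("dimension mismatch between ", path, " (", nrow(m), " x ",
           ncol(m), ") and companion file ", bad,
           " (features: ", length(genes), ", barcodes: ", length(cells), ")")
    }
    vals <- as.matrix(m)
    dimnames(vals) <- list(genes, cells)
  } else {
    df <- read.delim(path, check.names = FALSE, row.names = 1)
    vals <- t(as.matrix(df))  # file is cells x genes; flip to genes x cells
  }
  .validateCounts(vals, path)
  SingleCellExperiment(assays = list(counts = vals))
}

.validateCounts <- function(vals, path) {
  .stopIfNot(!anyNA(vals), "missing values in count matrix ", path)
  .stopIfNot(all(vals >= 0), "negative entry in count matrix ", path)
  .stopIfNot(all(vals == round(vals)), "non-integer entry in count matrix ",
             path)
  .stopIfNot(!anyDuplicated(rownames(vals)), "duplicate gene ids in ", path)
  .stopIfNot(!anyDuplicated(colnames(vals)), "duplicate cell ids in ", path)
  invisible(TRUE)
}

#' Write a count matrix
#'
#' Writes matrix-market triplet + companion files when `path` ends in
#' `.mtx`, otherwise a dense TSV with cells as rows and genes as columns
#' (header row of gene ids, first column of cell ids).
#'
#' @param x SingleCellExperiment (its `counts` assay) or genes x cells
#'   matrix.
#' @param path destination; `.mtx` selects the sparse triplet form.
#' @inheritParams readCounts
#' @return `path`, invisibly.
#' @export
writeCounts <- function(x, path,
                        features = file.path(dirname(path), "features.tsv"),
                        barcodes = file.path(dirname(path), "barcodes.tsv")) {
  m <- if (is(x, "SummarizedExperiment")) as.matrix(assay(x, "counts")) else
    as.matrix(x)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    writeMM(as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), path)
    writeLines(rownames(m), features)
    writeLines(colnames(m), barcodes)
  } else {
    df <- as.data.frame(t(m), check.names = FALSE)
    df <- cbind(cell_id = rownames(df), df)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read cluster labels
#'
#' Reads a two-column TSV (cell_id, subgroup label) into a named character
#' vector of labels.
#'
#' @param path TSV path; a header line `cell_id` is tolerated.
#' @return Named character vector, names are cell ids.
#' @export
readLabels <- function(path) {
  .stopIfNot(file.exists(path), "label file not found: ", path)
  df <- read.delim(path, header = FALSE, colClasses = "character")
  if (nrow(df) && df[1, 1] %in% c("cell_id", "cell", "barcode"))
    df <- df[-1, , drop = FALSE]
  .stopIfNot(nrow(df) > 0, "empty label file: ", path)
  .stopIfNot(ncol(df) >= 2, "label file needs two columns: ", path)
  dup <- df[[1]][duplicated(df[[1]])]
  if (length(dup))
    stop("duplicate cell ids in ", path, ": ",
         paste(head(unique(dup), 5), collapse = ", "))
  setNames(df[[2]], df[[1]])
}

#' Write cluster labels
#' @param labels named character vector (names are cell ids).
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
writeLabels <- function(labels, path) {
  write.table(data.frame(cell_id = names(labels), subgroup = labels),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Check labels against a matrix
#'
#' Reports cells labeled but absent from the matrix and cells of the matrix
#' missing a label.
#'
#' @param x SingleCellExperiment or matrix with cell ids as colnames.
#' @param labels named character vector of subgroup labels.
#' @return list with `unmatched_labels` and `unlabeled_cells`.
#' @export
validateLabels <- function(x, labels) {
  cells <- if (is(x, "SummarizedExperiment")) colnames(x) else colnames(x)
  list(unmatched_labels = setdiff(names(labels), cells),
       unlabeled_cells = setdiff(cells, names(labels)))
}

#' Attach labels to a SingleCellExperiment
#'
#' Matches labels to cells by id and stores them in `colData(x)$subgroup`.
#' Every labeled cell must exist in the matrix, every cell must get a
#' label, and every label must cover at least one cell.
#'
#' @param x SingleCellExperiment.
#' @param labels named character vector.
#' @return `x` with a `subgroup` colData column.
#' @export
addLabels <- function(x, labels) {
  chk <- validateLabels(x, labels)
  if (length(chk$unmatched_labels))
    stop("labels refer to cells absent from the matrix: ",
         paste(head(chk$unmatched_labels, 5), collapse = ", "))
  if (length(chk$unlabeled_cells))
    stop("cells without a label: ",
         paste(head(chk$unlabeled_cells, 5), collapse = ", "))
  colData(x)$subgroup <- unname(labels[colnames(x)])
  x
}

#' Read regulons from a GMT file
#'
#' Standard GMT: one gene set per line, fields `name`, `description`, then
#' tab-separated target gene ids. Duplicate genes within a line are
#' de-duplicated with a warning.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (regulon name -> target genes).
#' @export
readGMT <- function(path) {
  .stopIfNot(file.exists(path), "GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  .stopIfNot(length(lines) > 0, "empty GMT file: ", path)
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 fields in ", path)
    name <- f[[1]]
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in regulon '", name, "' de-duplicated")
      genes <- unique(genes)
    }
    if (name %in% names(out))
      stop("duplicate regulon name '", name, "' in ", path)
    out[[name]] <- genes
  }
  out
}

#' Write regulons to a GMT file
#' @param regulons named list of character vectors.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(regulons, path) {
  lines <- vapply(names(regulons), function(n)
    paste(c(n, "NA", regulons[[n]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a marker table to TSV
#'
#' Fixed column order (gene, subgroup, log2fc, p, p_adj, pct_in, pct_out);
#' numeric columns keep at least 6 significant digits. An empty table
#' yields a header-only file.
#'
#' @param x [MarkerTable] (or coercible data.frame).
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
writeMarkerTable <- function(x, path) {
  df <- as.data.frame(x)
  cols <- c("gene", "subgroup", "log2fc", "p", "p_adj", "pct_in", "pct_out")
  .stopIfNot(all(cols %in% colnames(df)), "marker table misses columns")
  df <- df[, cols]
  if (nrow(df) && !all(is.finite(df$log2fc)))
    stop("non-finite log2fc cannot be written")
  for (num in c("log2fc", "p", "p_adj", "pct_in", "pct_out"))
    df[[num]] <- formatC(df[[num]], digits = 8, format = "g")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker table from TSV
#'
#' @param path TSV written by [writeMarkerTable()] or an equivalent export;
#'   a missing `log2fc` column (figure-derived marker lists) is tolerated
#'   and filled with `NA`.
#' @param subgroups optional full subgroup universe (see [MarkerTable()]).
#' @return A [MarkerTable].
#' @export
readMarkerTable <- function(path, subgroups = NULL) {
  .stopIfNot(file.exists(path), "marker table not found: ", path)
  df <- read.delim(path, check.names = FALSE)
  .stopIfNot(all(c("gene", "subgroup") %in% colnames(df)),
             "marker table needs 'gene' and 'subgroup' columns: ", path)
  for (num in c("log2fc", "p", "p_adj", "pct_in", "pct_out"))
    if (!num %in% colnames(df))
      df[[num]] <- rep(NA_real_, nrow(df))
  mt <- as(as.data.frame(df), "DFrame")
  out <- new("MarkerTable", mt)
  metadata(out)$subgroups <-
    if (is.null(subgroups)) unique(as.character(df$subgroup)) else subgroups
  validObject(out)
  out
}
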