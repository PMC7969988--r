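# File-based pipeline drivers orchestrating the three analyses
# (concordance, tissue annotation, regulon differential activity) plus
# simulation, with YAML config, threshold provenance and run manifests.

#' Build a pipeline configuration
#'
#' Holds input/output paths and every threshold applied by the pipeline
#' drivers. Defaults are the package's canonical settings: marker
#' retention at log2 enrichment > 0.25 and adjusted p < 0.01, tie band
#' 0.8, AUCell top fraction 0.05, |z| selection threshold 2, signature
#' fold 2 with detection 0.5.
#'
#' @param ... named fields overriding the defaults; unknown fields are an
#'   error.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    counts_a = NULL, labels_a = NULL, markers_a = NULL,
    counts_b = NULL, labels_b = NULL, markers_b = NULL,
    query_counts = NULL, query_labels = NULL,
    ref_counts = NULL, ref_labels = NULL,
    regulons = NULL,
    log2fc_min = 0.25, p_adj_max = 0.01, min_pct = 0.1,
    tie_band = 0.8, top_fraction = 0.05, z_threshold = 2,
    fold_min = 2, detect_min = 0.5, top_k = 3,
    scale_factor = 1e4, gene_policy = "intersection",
    canonical_markers = hemocyteMarkers(),
    exclude_subgroups = character(), seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  .stopIfNot(!length(bad), "unknown config fields: ",
             paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  .validateConfig(cfg)
  structure(cfg, class = "PipelineConfig")
}

.validateConfig <- function(cfg) {
  .stopIfNot(cfg$log2fc_min >= 0, "log2fc_min must be >= 0")
  .stopIfNot(cfg$p_adj_max > 0 && cfg$p_adj_max <= 1,
             "p_adj_max must lie in (0, 1]")
  .stopIfNot(cfg$tie_band > 0 && cfg$tie_band <= 1,
             "tie_band must lie in (0, 1]")
  .stopIfNot(cfg$top_fraction > 0 && cfg$top_fraction < 1,
             "top_fraction must lie in (0, 1)")
  .stopIfNot(cfg$z_threshold > 0, "z_threshold must be positive")
  .stopIfNot(cfg$fold_min >= 1, "fold_min must be >= 1")
  .stopIfNot(cfg$detect_min >= 0 && cfg$detect_min <= 1,
             "detect_min must lie in [0, 1]")
  invisible(TRUE)
}

#' Read / write a pipeline configuration as YAML
#'
#' The round trip `readPipelineConfig(writePipelineConfig(cfg, f))` is
#' lossless.
#'
#' @param path YAML file.
#' @return `readPipelineConfig`: a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  .stopIfNot(file.exists(path), "config not found: ", path)
  vals <- yaml::read_yaml(path)
  vals$canonical_markers <- as.character(vals$canonical_markers)
  vals$exclude_subgroups <- as.character(vals$exclude_subgroups)
  do.call(pipelineConfig, vals)
}

#' @rdname readPipelineConfig
#' @param cfg a `PipelineConfig`.
#' @return `writePipelineConfig`: `path`, invisibly.
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

# Run manifest: thresholds actually applied, seed, input hashes, versions.
.writeManifest <- function(outdir, cfg, inputs, outputs, stage) {
  manifest <- list(
    stage = stage,
    package = as.character(packageVersion("scConcord")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = cfg$seed,
    thresholds = cfg[c("log2fc_min", "p_adj_max", "min_pct", "tie_band",
                       "top_fraction", "z_threshold", "fold_min",
                       "detect_min")],
    exclude_subgroups = cfg$exclude_subgroups,
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

.loadStudy <- function(countsPath, labelsPath, cfg) {
  sce <- readCounts(countsPath)
  sce <- addLabels(sce, readLabels(labelsPath))
  logNormalize(sce, cfg$scale_factor)
}

.loadMarkers <- function(cfg, side) {
  mk <- cfg[[paste0("markers_", side)]]
  if (!is.null(mk)) return(readMarkerTable(mk))
  cp <- cfg[[paste0("counts_", side)]]
  lp <- cfg[[paste0("labels_", side)]]
  .stopIfNot(!is.null(cp) && !is.null(lp),
             "need markers_", side, " or counts_", side, " + labels_", side)
  sce <- .loadStudy(cp, lp, cfg)
  findAllMarkers(sce, log2fcMin = cfg$log2fc_min, pAdjMax = cfg$p_adj_max,
                 minPct = cfg$min_pct)
}

.checkInputs <- function(paths) {
  paths <- unlist(paths)
  missing <- paths[!file.exists(paths)]
  .stopIfNot(!length(missing), "missing input file(s): ",
             paste(missing, collapse = ", "))
}

#' Run the cross-dataset concordance analysis
#'
#' Computes (or reads) the two marker tables, then the overlap matrix,
#' all paired enrichments of reciprocal best hits, and the consensus
#' correspondence; writes `markers_a.tsv`, `markers_b.tsv`,
#' `overlap.tsv`, `pairs_<a>_<b>.tsv`, `map.tsv` and `manifest.json` under
#' `outdir`.
#'
#' @param cfg a `PipelineConfig`; needs marker tables or counts+labels for
#'   sides a and b.
#' @param outdir output directory (created).
#' @return The [CorrespondenceMap], invisibly.
#' @export
runConcordance <- function(cfg, outdir) {
  .checkInputs(cfg[c("counts_a", "labels_a", "markers_a",
                     "counts_b", "labels_b", "markers_b")])
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mA <- .loadMarkers(cfg, "a")
  mB <- .loadMarkers(cfg, "b")
  writeMarkerTable(mA, file.path(outdir, "markers_a.tsv"))
  writeMarkerTable(mB, file.path(outdir, "markers_b.tsv"))
  map <- consensusMap(mA, mB, tieBand = cfg$tie_band,
                      excludeSubgroups = cfg$exclude_subgroups)
  ov <- overlapCounts(map)
  write.table(cbind(subgroup_a = rownames(ov), as.data.frame(ov)),
              file.path(outdir, "overlap.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  prs <- as.data.frame(correspondencePairs(map))
  for (i in which(prs$reciprocal_best)) {
    pe <- suppressWarnings(pairedEnrichment(
      mA, mB, prs$subgroup_a[i], prs$subgroup_b[i]))
    write.table(pe, file.path(outdir, sprintf("pairs_%s_%s.tsv",
                                              prs$subgroup_a[i],
                                              prs$subgroup_b[i])),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(prs, file.path(outdir, "map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  .writeManifest(outdir, cfg,
                 unlist(cfg[c("counts_a", "labels_a", "markers_a",
                              "counts_b", "labels_b", "markers_b")]),
                 list.files(outdir), "concordance")
  invisible(map)
}

#' Run the pseudo-bulk annotation analysis
#'
#' Builds pseudo-transcriptomes for query and reference, identifies
#' hemocyte-like clusters in the query by canonical markers, correlates
#' the pseudo-transcriptomes, ranks best matches, extracts the
#' query-specific signature of the top hemocyte cluster, and writes the
#' marker dot-plot data. Outputs: `hemocyte_evidence.tsv`,
#' `correlation.tsv`, `best_match.tsv`, `signature.tsv`, `dotplot.tsv`,
#' `manifest.json`.
#'
#' @param cfg a `PipelineConfig`; needs query and reference counts+labels.
#' @param outdir output directory (created).
#' @return list with the correlation matrix, best-match table, hemocyte
#'   call and signature, invisibly.
#' @export
runAnnotation <- function(cfg, outdir) {
  .checkInputs(cfg[c("query_counts", "query_labels", "ref_counts",
                     "ref_labels")])
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  qry <- .loadStudy(cfg$query_counts, cfg$query_labels, cfg)
  ref <- .loadStudy(cfg$ref_counts, cfg$ref_labels, cfg)
  ptQ <- pseudoTranscriptome(qry)
  ptR <- pseudoTranscriptome(ref)
  hemo <- withCallingHandlers(
    identifyHemocyteCluster(ptQ, cfg$canonical_markers),
    warning = function(w) { message("note: ", conditionMessage(w))
      invokeRestart("muffleWarning") })
  write.table(hemo$evidence, file.path(outdir, "hemocyte_evidence.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- correlatePseudo(ptQ, ptR, genePolicy = cfg$gene_policy)
  write.table(cbind(query = rownames(cm), as.data.frame(cm)),
              file.path(outdir, "correlation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  bm <- annotateBestMatch(cm, topK = cfg$top_k)
  write.table(bm, file.path(outdir, "best_match.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  target <- if (length(hemo$clusters)) hemo$clusters[1] else colnames(ptQ)[1]
  sig <- specificSignature(ptQ, ptR, queryColumn = target,
                           foldMin = cfg$fold_min,
                           detectMin = cfg$detect_min)
  write.table(sig, file.path(outdir, "signature.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dot <- markerDotData(ref, cfg$canonical_markers)
  write.table(dot, file.path(outdir, "dotplot.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  .writeManifest(outdir, cfg,
                 unlist(cfg[c("query_counts", "query_labels", "ref_counts",
                              "ref_labels")]),
                 list.files(outdir), "annotation")
  invisible(list(correlation = cm, best_match = bm, hemocytes = hemo,
                 signature = sig))
}

#' Run the regulon differential-activity analysis
#'
#' Scores regulon activity per cell (AUCell-style) and tests one-vs-rest
#' differential activity per cluster; writes `activity.tsv` (regulon x
#' cell AUC), `zscores.tsv` (regulon x cluster z, rows in clustered
#' order), `selected.tsv` and `manifest.json`.
#'
#' @param cfg a `PipelineConfig`; needs counts_a, labels_a and a regulons
#'   GMT path.
#' @param outdir output directory (created).
#' @return The differential-activity table, invisibly.
#' @export
runRegulon <- function(cfg, outdir) {
  .checkInputs(cfg[c("counts_a", "labels_a", "regulons")])
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sce <- .loadStudy(cfg$counts_a, cfg$labels_a, cfg)
  regs <- readGMT(cfg$regulons)
  act <- aucellScore(sce, regs, topFraction = cfg$top_fraction,
                     tieSeed = cfg$seed)
  A <- as.matrix(assay(act, "auc"))
  write.table(cbind(regulon = rownames(A), as.data.frame(A)),
              file.path(outdir, "activity.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  da <- differentialActivity(act, labels = colData(sce)$subgroup,
                             zThreshold = cfg$z_threshold)
  Z <- metadata(da)$zMatrix[metadata(da)$rowOrder, , drop = FALSE]
  write.table(cbind(regulon = rownames(Z), as.data.frame(Z)),
              file.path(outdir, "zscores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  sel <- as.data.frame(da)
  sel <- sel[sel$selected, , drop = FALSE]
  write.table(sel, file.path(outdir, "selected.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  .writeManifest(outdir, cfg,
                 unlist(cfg[c("counts_a", "labels_a", "regulons")]),
                 list.files(outdir), "regulon")
  invisible(da)
}

#' Simulate a study pair to disk
#'
#' Writes counts, labels and planted-marker tables of a synthetic study
#' pair (see [generateStudyPair()]) into `outdir`, for pipeline runs from
#' files.
#'
#' @param outdir output directory (created).
#' @param configA,configB `StudyConfig`s (defaults: [studyConfig()] with
#'   seeds `seed` and `seed + 1`).
#' @param sharedFraction,truthSeed see [generateStudyPair()].
#' @param seed base seed.
#' @return paths list, invisibly.
#' @export
simulatePairToDisk <- function(outdir, configA = NULL, configB = NULL,
                               sharedFraction = 0.6, truthSeed = 42,
                               seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(configA)) configA <- studyConfig(seed = seed)
  if (is.null(configB))
    configB <- studyConfig(seed = seed + 1, depthFactor = 0.6,
                           dropout = 0.2)
  pair <- generateStudyPair(configA, configB, sharedFraction, truthSeed)
  paths <- list(
    counts_a = file.path(outdir, "counts_a.tsv"),
    labels_a = file.path(outdir, "labels_a.tsv"),
    counts_b = file.path(outdir, "counts_b.tsv"),
    labels_b = file.path(outdir, "labels_b.tsv"),
    truth = file.path(outdir, "planted_map.tsv"))
  writeCounts(pair$studyA, paths$counts_a)
  writeLabels(setNames(colData(pair$studyA)$subgroup,
                       colnames(pair$studyA)), paths$labels_a)
  writeCounts(pair$studyB, paths$counts_b)
  writeLabels(setNames(colData(pair$studyB)$subgroup,
                       colnames(pair$studyB)), paths$labels_b)
  write.table(pair$correspondence, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
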