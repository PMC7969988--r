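# Synthetic multi-study scRNA-seq generator with planted ground truth.
#
# Counts are negative binomial with lognormal gene baselines; a planted
# marker multiplies its subgroup's mean by 2^log2fc; per-cell depth factors
# and independent Bernoulli dropout create study-specific detection
# differences. Ground truth (labels, planted markers, correspondence,
# regulon activity) is stored in metadata for downstream recovery tests.

#' Default hemocyte-like subgroup composition
#'
#' Eight subgroups mirroring a larval hemocyte atlas: a dominant
#' "unspecified" subgroup above 50%, several specified plasmatocyte
#' subgroups, a rare niche-like subgroup below 1%, plus crystal cells and
#' lamellocytes.
#'
#' @return Named numeric vector of proportions summing to 1.
#' @export
defaultProportions <- function() {
  c(unspecified   = 0.550,
    proliferative = 0.100,
    antimicrobial = 0.150,
    phagocytic    = 0.080,
    secretory     = 0.060,
    PSC_like      = 0.008,
    crystal       = 0.030,
    lamellocyte   = 0.022)
}

#' Build a study configuration
#'
#' @param nCells,nGenes study dimensions.
#' @param proportions named subgroup proportions; must sum to 1 within
#'   1e-9.
#' @param nMarkers planted marker genes per subgroup.
#' @param markerLog2FC range (length-2) of planted log2 enrichments, drawn
#'   uniformly per marker; all values must be >= 0.
#' @param baselineMeanlog,baselineSdlog lognormal parameters of baseline
#'   per-gene mean counts.
#' @param markerMeanlog,markerSdlog lognormal parameters of marker-gene
#'   baselines (markers are modelled as moderately expressed genes).
#' @param dispersion negative binomial size parameter; `Inf` gives the
#'   Poisson limit.
#' @param depthFactor study-wide sequencing-depth multiplier.
#' @param depthSdlog lognormal sd of per-cell depth jitter (0 disables).
#' @param dropout probability that an observed count is zeroed
#'   (independent Bernoulli, applied after the count draw).
#' @param seed integer seed; a fixed seed makes the draw byte-identical.
#' @return A list of class `StudyConfig`.
#' @export
studyConfig <- function(nCells = 2000, nGenes = 2000,
                        proportions = defaultProportions(),
                        nMarkers = 20, markerLog2FC = c(1, 4),
                        baselineMeanlog = 0, baselineSdlog = 1,
                        markerMeanlog = log(2), markerSdlog = 0.5,
                        dispersion = 2, depthFactor = 1, depthSdlog = 0.25,
                        dropout = 0.1, seed = 1) {
  .stopIfNot(abs(sum(proportions) - 1) <= 1e-9,
             "subgroup proportions must sum to 1 (tolerance 1e-9)")
  .stopIfNot(!is.null(names(proportions)) && !anyDuplicated(names(proportions)),
             "proportions must carry unique subgroup names")
  .stopIfNot(all(markerLog2FC >= 0), "planted log2 enrichments must be >= 0")
  .stopIfNot(dropout >= 0 && dropout < 1, "dropout must lie in [0, 1)")
  .stopIfNot(dispersion > 0, "dispersion must be positive")
  .stopIfNot(depthFactor > 0, "depthFactor must be positive")
  structure(list(nCells = nCells, nGenes = nGenes, proportions = proportions,
                 nMarkers = nMarkers, markerLog2FC = markerLog2FC,
                 baselineMeanlog = baselineMeanlog,
                 baselineSdlog = baselineSdlog,
                 markerMeanlog = markerMeanlog, markerSdlog = markerSdlog,
                 dispersion = dispersion, depthFactor = depthFactor,
                 depthSdlog = depthSdlog, dropout = dropout, seed = seed),
            class = "StudyConfig")
}

# Draw the shared "biology": which genes mark which subgroup, at what
# planted log2fc. Marker sets are disjoint across subgroups.
.drawBiology <- function(nGenes, subgroups, nMarkers, l2fcRange, seed) {
  .withSeed(seed, {
    genes <- .geneIds(nGenes)
    need <- nMarkers * length(subgroups)
    .stopIfNot(need <= nGenes, "not enough genes for the planted markers")
    pool <- sample(genes, need)
    markers <- data.frame(
      gene = pool,
      subgroup = rep(subgroups, each = nMarkers),
      log2fc = runif(need, l2fcRange[1], l2fcRange[2]),
      stringsAsFactors = FALSE)
    markers
  })
}

.geneIds <- function(nGenes) sprintf("g%05d", seq_len(nGenes))

#' Generate one synthetic study
#'
#' Draws subgroup labels multinomially, plants `nMarkers` marker genes per
#' subgroup at the configured log2 enrichments, and samples counts from a
#' negative binomial whose mean is `baseline * 2^log2fc (marker pairs) *
#' cell depth`. Subgroups whose realized size falls below 5 cells are
#' topped up from the largest subgroup (with a message) so downstream
#' statistics stay defined.
#'
#' @param config A `StudyConfig` from [studyConfig()].
#' @param biology optional shared biology: a planted-marker table (gene,
#'   subgroup, log2fc) or a list with elements `markers` (that table) and
#'   `baseline` (named per-gene mean vector). Supply to share marker
#'   identities and expression baselines across studies of the same
#'   population (see [generateStudyPair()]).
#' @param cellPrefix prefix for cell ids.
#' @return A [SingleCellExperiment::SingleCellExperiment] with `counts`,
#'   true labels in `colData()$subgroup`, and ground truth in
#'   `metadata()$groundTruth` (planted marker table, baseline means,
#'   per-cell depths, dispersion, dropout).
#' @examples
#' sce <- generateStudy(studyConfig(nCells = 200, nGenes = 100, seed = 7))
#' table(colData(sce)$subgroup)
#' @export
generateStudy <- function(config, biology = NULL, cellPrefix = "cell") {
  .stopIfNot(inherits(config, "StudyConfig"), "config must be a StudyConfig")
  subgroups <- names(config$proportions)
  genes <- .geneIds(config$nGenes)
  if (is.null(biology))
    biology <- .drawBiology(config$nGenes, subgroups, config$nMarkers,
                            config$markerLog2FC, config$seed + 7919L)
  sharedBaseline <- NULL
  if (is.list(biology) && !is.data.frame(biology)) {
    sharedBaseline <- biology$baseline
    biology <- biology$markers
  }
  .stopIfNot(all(biology$gene %in% genes),
             "planted marker gene not in gene universe")
  .stopIfNot(is.null(sharedBaseline) ||
               identical(sort(names(sharedBaseline)), sort(genes)),
             "shared baseline must cover the gene universe")
  .withSeed(config$seed, {
    n <- config$nCells
    labels <- sample(subgroups, n, replace = TRUE, prob = config$proportions)
    # rare-subgroup floor: any expected-positive subgroup keeps >= 5 cells
    tab <- table(factor(labels, levels = subgroups))
    for (sg in subgroups[tab < 5 & config$proportions > 0]) {
      deficit <- 5 - sum(labels == sg)
      if (deficit > 0) {
        donor <- names(which.max(table(labels)))
        idx <- sample(which(labels == donor), deficit)
        labels[idx] <- sg
        message("subgroup '", sg, "' resampled up to 5 cells")
      }
    }
    if (is.null(sharedBaseline)) {
      baseline <- rlnorm(config$nGenes, config$baselineMeanlog,
                         config$baselineSdlog)
      names(baseline) <- genes
      mk <- unique(biology$gene)
      baseline[mk] <- rlnorm(length(mk), config$markerMeanlog,
                             config$markerSdlog)
    } else {
      baseline <- sharedBaseline[genes]
    }
    depth <- config$depthFactor *
      if (config$depthSdlog > 0) rlnorm(n, 0, config$depthSdlog) else rep(1, n)
    fc <- matrix(0, config$nGenes, length(subgroups),
                 dimnames = list(genes, subgroups))
    fc[cbind(match(biology$gene, genes),
             match(biology$subgroup, subgroups))] <- biology$log2fc
    counts <- matrix(0L, config$nGenes, n,
                     dimnames = list(genes, sprintf("%s%05d", cellPrefix,
                                                    seq_len(n))))
    for (sg in subgroups) {
      idx <- which(labels == sg)
      if (!length(idx)) next
      muG <- baseline * 2^fc[, sg]
      mu <- outer(muG, depth[idx])
      counts[, idx] <- .drawCounts(mu, config$dispersion)
    }
    if (config$dropout > 0) {
      keep <- matrix(rbinom(length(counts), 1, 1 - config$dropout),
                     nrow(counts))
      counts <- counts * keep
    }
    storage.mode(counts) <- "integer"
    sce <- SingleCellExperiment(assays = list(counts = counts))
    colData(sce)$subgroup <- labels
    metadata(sce)$groundTruth <- list(
      markers = biology, baseline = baseline, depth = depth,
      labels = setNames(labels, colnames(sce)),
      dispersion = config$dispersion, dropout = config$dropout,
      config = config)
    sce
  })
}

.drawCounts <- function(mu, dispersion) {
  if (is.finite(dispersion))
    matrix(rnbinom(length(mu), size = dispersion, mu = mu), nrow(mu))
  else
    matrix(rpois(length(mu), mu), nrow(mu))
}

#' Generate a pair of studies with a planted correspondence
#'
#' Both studies describe the same subgroup biology: they share per-gene
#' baseline expression means, and each subgroup keeps a configurable
#' fraction of its planted markers in common between the two studies
#' (identical genes at identical planted log2fc), while the rest are
#' study-specific; sequencing depth, dropout and the count noise differ
#' per config. The planted correspondence is the identity on subgroup
#' names, returned explicitly.
#'
#' @param configA,configB `StudyConfig`s sharing `nGenes` and subgroup
#'   names.
#' @param sharedFraction fraction of each subgroup's markers common to the
#'   two studies (default 0.6).
#' @param truthSeed seed for the shared biology draw (marker identities
#'   and enrichments), independent of the per-study sampling seeds.
#' @return list with elements `studyA`, `studyB` (SingleCellExperiments as
#'   from [generateStudy()]) and `correspondence` (data.frame subgroup_a,
#'   subgroup_b).
#' @export
generateStudyPair <- function(configA, configB, sharedFraction = 0.6,
                              truthSeed = 42) {
  .stopIfNot(configA$nGenes == configB$nGenes,
             "studies must share one gene universe (equal nGenes)")
  .stopIfNot(identical(names(configA$proportions), names(configB$proportions)),
             "studies must share subgroup names")
  .stopIfNot(sharedFraction >= 0 && sharedFraction <= 1,
             "sharedFraction must lie in [0, 1]")
  subgroups <- names(configA$proportions)
  nm <- configA$nMarkers
  .stopIfNot(nm == configB$nMarkers,
             "configs must plant the same number of markers")
  nShared <- round(sharedFraction * nm)
  bio <- .withSeed(truthSeed, {
    genes <- .geneIds(configA$nGenes)
    need <- length(subgroups) * (nShared + 2 * (nm - nShared))
    .stopIfNot(need <= length(genes),
               "not enough genes for the planted marker sets")
    pool <- sample(genes, need)
    rows <- list()
    off <- 0
    for (sg in subgroups) {
      shared <- pool[off + seq_len(nShared)]; off <- off + nShared
      onlyA <- pool[off + seq_len(nm - nShared)]; off <- off + (nm - nShared)
      onlyB <- pool[off + seq_len(nm - nShared)]; off <- off + (nm - nShared)
      l2Shared <- runif(nShared, configA$markerLog2FC[1],
                        configA$markerLog2FC[2])
      l2A <- runif(nm - nShared, configA$markerLog2FC[1],
                   configA$markerLog2FC[2])
      l2B <- runif(nm - nShared, configB$markerLog2FC[1],
                   configB$markerLog2FC[2])
      rows[[sg]] <- list(
        A = data.frame(gene = c(shared, onlyA), subgroup = sg,
                       log2fc = c(l2Shared, l2A)),
        B = data.frame(gene = c(shared, onlyB), subgroup = sg,
                       log2fc = c(l2Shared, l2B)))
    }
    mkA <- do.call(rbind, lapply(rows, `[[`, "A"))
    mkB <- do.call(rbind, lapply(rows, `[[`, "B"))
    baseline <- rlnorm(configA$nGenes, configA$baselineMeanlog,
                       configA$baselineSdlog)
    names(baseline) <- genes
    mk <- unique(c(mkA$gene, mkB$gene))
    baseline[mk] <- rlnorm(length(mk), configA$markerMeanlog,
                           configA$markerSdlog)
    list(A = mkA, B = mkB, baseline = baseline)
  })
  a <- generateStudy(configA,
                     biology = list(markers = bio$A,
                                    baseline = bio$baseline),
                     cellPrefix = "A")
  b <- generateStudy(configB,
                     biology = list(markers = bio$B,
                                    baseline = bio$baseline),
                     cellPrefix = "B")
  list(studyA = a, studyB = b,
       correspondence = data.frame(subgroup_a = subgroups,
                                   subgroup_b = subgroups,
                                   stringsAsFactors = FALSE))
}

#' Plant regulon activity into a synthetic study
#'
#' Re-draws the counts of regulon target genes in the subgroups where the
#' regulon is designated active, with the negative-binomial mean scaled by
#' `2^effectLog2FC`; all other entries are untouched. With effect 0 the
#' matrix is unchanged in distribution.
#'
#' @param sce a synthetic study from [generateStudy()] (its ground-truth
#'   metadata supplies baselines and depths).
#' @param regulons named list of target gene vectors.
#' @param activeMap named list: regulon name -> character vector of
#'   subgroups where the regulon is active.
#' @param effectLog2FC log2 scaling of the target-gene means in active
#'   subgroups.
#' @param seed seed for the re-draw.
#' @return The modified SingleCellExperiment; `metadata()$groundTruth$
#'   regulons` records the active map and effect.
#' @export
plantRegulons <- function(sce, regulons, activeMap, effectLog2FC = 2,
                          seed = 1) {
  gt <- metadata(sce)$groundTruth
  .stopIfNot(!is.null(gt), "sce carries no ground truth; use generateStudy()")
  .stopIfNot(all(names(activeMap) %in% names(regulons)),
             "activeMap names must be regulon names")
  genes <- rownames(sce)
  labels <- colData(sce)$subgroup
  counts <- as.matrix(assay(sce, "counts"))
  fcOf <- function(g, sg) {
    m <- gt$markers
    hit <- m$gene == g & m$subgroup == sg
    if (any(hit)) m$log2fc[hit][1] else 0
  }
  .withSeed(seed, {
    for (rg in names(activeMap)) {
      targets <- regulons[[rg]]
      missing <- setdiff(targets, genes)
      if (length(missing))
        stop("regulon '", rg, "' targets absent from gene universe: ",
             paste(head(missing, 5), collapse = ", "))
      for (sg in activeMap[[rg]]) {
        idx <- which(labels == sg)
        if (!length(idx)) next
        for (g in targets) {
          mu <- gt$baseline[g] * 2^(fcOf(g, sg) + effectLog2FC) * gt$depth[idx]
          newc <- .drawCounts(matrix(mu, nrow = 1), gt$dispersion)[1, ]
          if (gt$dropout > 0)
            newc <- newc * rbinom(length(newc), 1, 1 - gt$dropout)
          counts[g, idx] <- as.integer(newc)
        }
      }
    }
  })
  assay(sce, "counts") <- counts
  gt$regulons <- list(activeMap = activeMap, effectLog2FC = effectLog2FC)
  metadata(sce)$groundTruth <- gt
  sce
}

#' Ground truth of a synthetic study
#' @param sce a SingleCellExperiment from [generateStudy()].
#' @return The ground-truth list (planted markers, labels, baselines, ...).
#' @export
groundTruth <- function(sce) metadata(sce)$groundTruth
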