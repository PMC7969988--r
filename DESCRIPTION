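Package: scConcord
Title: Cross-Dataset Concordance of Single-Cell Subgroups
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for harmonizing cell subgroups across independent
    single-cell RNA-seq studies of the same population, developed around
    Drosophila larval hemocyte atlases. Implements Wilcoxon rank-sum marker
    detection with log2-enrichment and adjusted-p thresholds, marker-overlap
    and specificity-weighted subgroup matching with reciprocal best hits,
    pseudo-bulk Pearson-correlation annotation of cells found in other
    tissues or stages, AUCell-style regulon activity scoring with
    Mann-Whitney differential activity, and a negative-binomial synthetic
    multi-study generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
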