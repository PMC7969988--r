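test_that("pseudo-transcriptome columns are per-subgroup means", {
  m <- matrix(c(2L, 0L, 4L,
                1L, 3L, 5L,
                0L, 2L, 2L), 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2", "c3")))
  norm <- logNormalize(m)
  pt <- pseudoTranscriptome(norm, labels = c("a", "a", "b"))
  expm <- expm1(norm)
  expect_equal(assay(pt, "avgExpr")[, "a"], rowMeans(expm[, 1:2]),
               tolerance = 1e-12)
  expect_equal(assay(pt, "avgExpr")[, "b"], expm[, 3], tolerance = 1e-12)
  expect_identical(colData(pt)$nCells, c(2L, 1L))

  # one cell per subgroup: the column is that cell's profile
  pt1 <- pseudoTranscriptome(norm, labels = c("x", "y", "z"))
  expect_equal(assay(pt1, "avgExpr")[, "y"], expm[, 2], tolerance = 1e-12)

  # all cells identical: every column identical
  same <- logNormalize(matrix(3L, 4, 6,
                              dimnames = list(paste0("g", 1:4),
                                              paste0("c", 1:6))))
  ptS <- pseudoTranscriptome(same, labels = rep(c("a", "b", "c"), 2))
  expect_equal(assay(ptS, "avgExpr")[, "a"], assay(ptS, "avgExpr")[, "c"])
})

test_that("Pearson correlation matches the closed-form oracle", {
  set.seed(44)
  avgQ <- matrix(rexp(200), 100, 2,
                 dimnames = list(sprintf("g%03d", 1:100), c("q1", "q2")))
  avgR <- matrix(rexp(300), 100, 3,
                 dimnames = list(sprintf("g%03d", 1:100), c("r1", "r2", "r3")))
  M <- correlatePseudo(ptFrom(avgQ), ptFrom(avgR))
  x <- log1p(avgQ[, "q2"]); y <- log1p(avgR[, "r3"])
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(M["q2", "r3"], manual, tolerance = 1e-12)
  expect_identical(attr(M, "n_genes"), 100L)

  # identical columns correlate at exactly 1
  expect_equal(correlatePseudo(ptFrom(avgQ), ptFrom(avgQ))["q1", "q1"], 1)

  # exact anti-correlation on the log scale
  r <- c(0.5, 1, 2, 4, 8)
  anti <- expm1(max(log1p(r)) + min(log1p(r)) - log1p(r))
  avg2 <- cbind(ref = r, anti = anti)
  rownames(avg2) <- paste0("g", 1:5)
  M2 <- correlatePseudo(ptFrom(avg2[, "anti", drop = FALSE]),
                        ptFrom(avg2[, "ref", drop = FALSE]))
  expect_equal(M2["anti", "ref"], -1, tolerance = 1e-12)
})

test_that("correlation is symmetric and ignores gene order", {
  set.seed(45)
  avgQ <- matrix(rexp(60), 30, 2,
                 dimnames = list(sprintf("g%02d", 1:30), c("q1", "q2")))
  avgR <- matrix(rexp(60), 30, 2,
                 dimnames = list(sprintf("g%02d", 1:30), c("r1", "r2")))
  expect_equal(correlatePseudo(ptFrom(avgQ), ptFrom(avgR)),
               t(correlatePseudo(ptFrom(avgR), ptFrom(avgQ))),
               ignore_attr = TRUE)
  perm <- sample(30)
  expect_equal(
    correlatePseudo(ptFrom(avgQ[perm, ]), ptFrom(avgR)),
    correlatePseudo(ptFrom(avgQ), ptFrom(avgR)), ignore_attr = TRUE)
})

test_that("degenerate correlation inputs are handled explicitly", {
  avg <- matrix(1:12, 4, 3, dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  two <- avg[1:2, ]
  expect_error(correlatePseudo(ptFrom(two), ptFrom(two)), "fewer than 3")
  flat <- avg; flat[, 2] <- 5
  expect_warning(M <- correlatePseudo(ptFrom(avg), ptFrom(flat)),
                 "zero-variance")
  expect_true(all(is.na(M[, 2])))
  expect_false(anyNA(M[, c(1, 3)]))
})

test_that("best-match ranking reports margins and breaks ties predictably", {
  M <- rbind(q1 = c(b = 0.9, a = 0.9, c = 0.2))
  bm <- annotateBestMatch(M, topK = 2)
  expect_identical(bm$reference, c("a", "b"))  # lexicographic on ties
  expect_true(all(bm$tie[1:2]))
  one <- annotateBestMatch(rbind(q = c(only = 0.5)), topK = 3)
  expect_identical(one$reference, "only")
  expect_true(is.na(one$margin))
})

test_that("a noisy copy of a reference subgroup is annotated back to it", {
  set.seed(46)
  sce <- logNormalize(generateStudy(quadConfig(seed = 47)))
  ptR <- pseudoTranscriptome(sce)
  hits <- vapply(1:20, function(i) {
    q <- assay(ptR, "avgExpr")[, "sg3", drop = FALSE] *
      matrix(rlnorm(nrow(ptR), 0, 0.3), ncol = 1)
    colnames(q) <- "query"
    M <- correlatePseudo(ptFrom(q), ptR)
    annotateBestMatch(M, topK = 1)$reference == "sg3"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("self-annotation returns the identity with unit diagonal", {
  sce <- logNormalize(generateStudy(quadConfig(seed = 48)))
  pt <- pseudoTranscriptome(sce)
  M <- correlatePseudo(pt, pt)
  expect_equal(unname(diag(M)), rep(1, 4))
  bm <- annotateBestMatch(M, topK = 1)
  expect_identical(bm$query, bm$reference)
})

test_that("canonical-marker scoring singles out the hemocyte cluster", {
  genes <- c(hemocyteMarkers(), paste0("g", 1:10))
  set.seed(49)
  avg <- matrix(runif(length(genes) * 4, 0, 2), length(genes), 4,
                dimnames = list(genes, paste0("cl", 1:4)))
  avg[hemocyteMarkers(), "cl2"] <- 10 * apply(avg[hemocyteMarkers(), ], 1, max)
  res <- identifyHemocyteCluster(ptFrom(avg))
  expect_identical(res$clusters, "cl2")
  expect_equal(res$evidence$score[res$evidence$cluster == "cl2"], 1.0)

  # no marker expressed anywhere: empty call plus warning, not an error
  none <- avg[paste0("g", 1:10), ]
  expect_warning(r0 <- identifyHemocyteCluster(ptFrom(none)), "no canonical")
  expect_identical(r0$clusters, character())

  # two clusters splitting the markers: neither passes, both in evidence
  split <- matrix(0, length(genes), 2,
                  dimnames = list(genes, c("clA", "clB")))
  split[hemocyteMarkers()[1:4], "clA"] <- 5
  split[hemocyteMarkers()[5:7], "clB"] <- 5
  expect_warning(rs <- identifyHemocyteCluster(ptFrom(split)), "no cluster")
  expect_identical(rs$clusters, character())
  expect_setequal(rs$evidence$cluster, c("clA", "clB"))
})

test_that("specific signatures obey the fold and detection rules", {
  genes <- paste0("g", 1:6)
  ref <- matrix(1, 6, 3, dimnames = list(genes, paste0("r", 1:3)))
  # graded folds on the pseudocount-1 scale: (q+1)/(max_ref+1)
  q <- matrix((1 + 1) * c(1.5, 2, 2.5, 1, 1, 1) - 1, ncol = 1,
              dimnames = list(genes, "q"))
  det <- matrix(c(1, 1, 1, 1, 1, 0.2), ncol = 1,
                dimnames = list(genes, "q"))
  sig <- specificSignature(ptFrom(q, detection = det), ptFrom(ref))
  expect_identical(sig$gene, c("g3", "g2"))  # boundary 2.0 inclusive

  # identical to a reference column: nothing specific
  same <- ref[, 1, drop = FALSE]; colnames(same) <- "q"
  expect_identical(nrow(specificSignature(ptFrom(same), ptFrom(ref))), 0L)

  # one planted query-only gene
  solo <- ref[, 1, drop = FALSE] ; colnames(solo) <- "q"
  solo["g4", 1] <- 50
  sig2 <- specificSignature(ptFrom(solo), ptFrom(ref))
  expect_identical(sig2$gene, "g4")
})

test_that("dot-plot data report mean expression and detection per subgroup", {
  sce <- logNormalize(generateStudy(quadConfig(seed = 50)))
  genes <- rownames(sce)[1:3]
  dd <- markerDotData(sce, genes)
  expect_identical(nrow(dd), 12L)
  expect_true(all(dd$pct_expr >= 0 & dd$pct_expr <= 1))
  pt <- pseudoTranscriptome(sce)
  expect_equal(dd$mean_expr[dd$gene == genes[2] & dd$subgroup == "sg1"],
               unname(assay(pt, "avgExpr")[genes[2], "sg1"]))
})
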