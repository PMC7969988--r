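test_that("overlap counts equal brute-force set intersection", {
  set.seed(8)
  genes <- sprintf("g%03d", 1:60)
  tA <- mkTable(gene = sample(genes, 40), subgroup = rep(c("a1", "a2"), 20))
  tB <- mkTable(gene = sample(genes, 40), subgroup = rep(c("b1", "b2"), 20))
  O <- overlapMatrix(tA, tB)
  for (a in c("a1", "a2")) for (b in c("b1", "b2")) {
    ga <- tA$gene[tA$subgroup == a]; gb <- tB$gene[tB$subgroup == b]
    expect_identical(O[a, b], length(intersect(ga, gb)))
    expect_lte(O[a, b], min(length(ga), length(gb)))
  }
})

test_that("disjoint marker sets give a zero matrix, self-overlap the sizes", {
  tA <- mkTable(gene = paste0("x", 1:10), subgroup = rep(c("a1", "a2"), 5))
  tB <- mkTable(gene = paste0("y", 1:10), subgroup = rep(c("b1", "b2"), 5))
  expect_true(all(overlapMatrix(tA, tB) == 0))
  expect_identical(attr(overlapMatrix(tA, tB), "unmatched_a"), 10L)
  O <- overlapMatrix(tA, tA)
  expect_identical(unname(diag(O)), c(5L, 5L))
})

test_that("paired enrichment returns shared genes with both log2fc values", {
  tA <- mkTable(gene = c("g1", "g2", "g3"), subgroup = "a",
                log2fc = c(2, 1, 3))
  tB <- mkTable(gene = c("g2", "g3", "g4"), subgroup = "b",
                log2fc = c(4, 0.5, 1))
  pe <- pairedEnrichment(tA, tB, "a", "b")
  expect_identical(pe$gene, c("g2", "g3"))  # sorted by min(log2fc) desc
  expect_equal(pe$log2fc_a, c(1, 3))
  expect_equal(pe$log2fc_b, c(4, 0.5))
  # identical tables lie on the diagonal
  d <- pairedEnrichment(tA, tA, "a", "a")
  expect_equal(d$log2fc_a, d$log2fc_b)
  # no shared markers: empty with a warning
  tC <- mkTable(gene = "zz", subgroup = "c")
  expect_warning(e <- pairedEnrichment(tA, tC, "a", "c"), "share no")
  expect_identical(nrow(e), 0L)
})

test_that("match score is linear in enrichment and rewards specificity", {
  pe <- data.frame(gene = paste0("g", 1:10), log2fc_a = 1, log2fc_b = 1)
  specific <- setNames(rep(0.1, 10), pe$gene)
  ubiquitous <- setNames(rep(1, 10), pe$gene)
  sSpec <- matchScore(pe, specific, specific, Kbar = 10)
  sUbiq <- matchScore(pe, ubiquitous, ubiquitous, Kbar = 10)
  expect_gt(sSpec, sUbiq)
  expect_equal(matchScore(pe[0, ], specific, specific, 10), 0)
  pe2 <- pe; pe2$log2fc_a <- 2 * pe2$log2fc_a; pe2$log2fc_b <- 2 * pe2$log2fc_b
  expect_equal(matchScore(pe2, specific, specific, 10), 2 * sSpec)
})

test_that("few specific shared markers beat many ubiquitous ones", {
  # subgroup a shares 10 ubiquitous markers with b1 but only 3 fully
  # specific ones with b2: the specific evidence must win
  sgA <- paste0("a", 1:5); sgB <- paste0("b", 1:5)
  ubiq <- paste0("u", 1:10); specf <- paste0("s", 1:3)
  tA <- mkTable(
    gene = c(rep(ubiq, 5), specf, paste0("fillA", 1:4)),
    subgroup = c(rep(sgA, each = 10), rep("a1", 3), sgA[2:5]),
    subgroups = sgA)
  tB <- mkTable(
    gene = c(ubiq, specf, paste0("fillB", 1:4)),
    subgroup = c(rep("b1", 10), rep("b2", 3), sgB[2:5]),
    subgroups = sgB)
  map <- consensusMap(tA, tB)
  prs <- as.data.frame(correspondencePairs(map))
  expect_identical(prs$subgroup_b[prs$subgroup_a == "a1"], "b2")
})

test_that("identical datasets map to themselves with reciprocal best hits", {
  set.seed(12)
  t <- mkTable(gene = sprintf("g%03d", 1:40),
               subgroup = rep(paste0("s", 1:4), each = 10),
               log2fc = runif(40, 0.5, 3))
  map <- consensusMap(t, t)
  prs <- as.data.frame(correspondencePairs(map))
  expect_identical(prs$subgroup_a, prs$subgroup_b)
  expect_true(all(prs$reciprocal_best))
  expect_true(all(prs$tie_partners == ""))
})

test_that("the map is symmetric under swapping dataset roles", {
  set.seed(19)
  genes <- sprintf("g%03d", 1:80)
  tA <- mkTable(gene = sample(genes, 60),
                subgroup = rep(paste0("a", 1:3), each = 20),
                log2fc = runif(60, 0.5, 4))
  tB <- mkTable(gene = sample(genes, 60),
                subgroup = rep(paste0("b", 1:3), each = 20),
                log2fc = runif(60, 0.5, 4))
  ab <- consensusMap(tA, tB)
  ba <- consensusMap(tB, tA)
  expect_equal(scoreMatrix(ab), t(scoreMatrix(ba)))
  rb1 <- reciprocalBestHits(ab)
  rb2 <- reciprocalBestHits(ba)
  expect_setequal(paste(rb1$subgroup_a, rb1$subgroup_b),
                  paste(rb2$subgroup_b, rb2$subgroup_a))
})

test_that("scores ignore marker-row ordering", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:50)
  tA <- mkTable(gene = sample(genes, 30),
                subgroup = rep(c("a1", "a2"), 15),
                log2fc = runif(30, 0.5, 3))
  tB <- mkTable(gene = sample(genes, 30),
                subgroup = rep(c("b1", "b2"), 15),
                log2fc = runif(30, 0.5, 3))
  shuf <- MarkerTable(as.data.frame(tA)[sample(30), ],
                      subgroups = metadata(tA)$subgroups)
  expect_equal(scoreMatrix(consensusMap(tA, tB)),
               scoreMatrix(consensusMap(shuf, tB)))
})

test_that("excluded subgroups are dropped before comparison", {
  t <- mkTable(gene = sprintf("g%03d", 1:30),
               subgroup = rep(c("s1", "s2", "wound"), each = 10))
  map <- consensusMap(t, t, excludeSubgroups = "wound")
  expect_false("wound" %in% rownames(scoreMatrix(map)))
  expect_false("wound" %in% colnames(scoreMatrix(map)))
})

test_that("trajectory-root disagreement is annotated, never dropped", {
  t <- mkTable(gene = sprintf("g%03d", 1:20),
               subgroup = rep(c("s1", "s2"), each = 10))
  map <- consensusMap(t, t,
                      trajectoryRoots = list(a = "s1", b = "s2"))
  prs <- as.data.frame(correspondencePairs(map))
  expect_true(all(c("s1", "s2") %in% prs$subgroup_a))
  expect_identical(prs$trajectory_discordant[prs$subgroup_a == "s1"], TRUE)
  expect_identical(prs$trajectory_discordant[prs$subgroup_a == "s2"], TRUE)
})

test_that("figure-derived tables fall back to overlap-count scoring", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "fu.tsv")
  writeLines(c("gene\tsubgroup", "PPO1\tcrystal", "PPO2\tcrystal",
               "atilla\tlamellocyte"), p)
  fu <- readMarkerTable(p)
  full <- mkTable(gene = c("PPO1", "PPO2", "lz", "atilla", "mys"),
                  subgroup = c(rep("CC", 3), rep("LM", 2)),
                  log2fc = c(4, 4, 2, 5, 1))
  map <- consensusMap(fu, full)
  S <- scoreMatrix(map)
  expect_equal(S["crystal", "CC"], 2)  # shared-marker count
  expect_equal(S["lamellocyte", "LM"], 1)
})

test_that("a small planted study pair is matched end-to-end", {
  pair <- generateStudyPair(quadConfig(seed = 71),
                            quadConfig(seed = 72, dropout = 0.2),
                            sharedFraction = 0.6, truthSeed = 73)
  mA <- findAllMarkers(logNormalize(pair$studyA))
  mB <- findAllMarkers(logNormalize(pair$studyB))
  rb <- reciprocalBestHits(consensusMap(mA, mB))
  expect_identical(nrow(rb), 4L)
  expect_identical(rb$subgroup_a, rb$subgroup_b)
})
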