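test_that("length-normalised ranking divides by length and breaks ties", {
  r <- rankByLengthNormalized(c(A = 100, B = 30), c(A = 10, B = 1))
  expect_equal(r$gene_id, c("B", "A"))
  expect_equal(r$normalized, c(30, 10))
  expect_equal(r$rank, 1:2)

  ## ties: raw count descending, then gene id; invariant to input order
  cnt <- c(x2 = 20, x1 = 20, y = 10, z = 40)
  len <- c(x2 = 2, x1 = 2, y = 1, z = 4)
  r1 <- rankByLengthNormalized(cnt, len)
  r2 <- rankByLengthNormalized(rev(cnt), len)
  expect_identical(r1, r2)
  expect_equal(r1$gene_id, c("z", "x1", "x2", "y"))

  expect_warning(r3 <- rankByLengthNormalized(c(A = 5, B = 5), c(A = 1)),
                 "1 gene")
  expect_equal(r3$gene_id, "A")
})

test_that("the vectorised rank-sum test matches stats::wilcox.test", {
  set.seed(202)
  grp <- rep(c(TRUE, FALSE), c(15, 25))
  for (i in 1:20) {
    v <- rnbinom(40, mu = 4, size = 2)           # heavy ties, like counts
    mine <- gagaTargets:::.rowWilcox(matrix(v, 1), grp)
    ref <- suppressWarnings(
      wilcox.test(v[grp], v[!grp], exact = FALSE, correct = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("markers are detected for planted genes but not identical ones", {
  sc <- generateScCounts(303, nClusters = 3, cellsPerCluster = 60,
                         nGenes = 150, markersPerCluster = 4, fold = 8,
                         clusterIds = c("1", "2", "3"))
  mk <- findMarkers(sc$counts, sc$clusters)
  expect_true(all(mk$p_adj >= mk$p))
  expect_true(all(mk$frac_in >= 0 & mk$frac_in <= 1))
  found <- mk[mk$is_marker & mk$effect > 0, c("gene_id", "cluster")]
  planted <- paste(sc$truth$gene_id, sc$truth$cluster)
  expect_true(all(planted %in% paste(found$gene_id, found$cluster)))

  ## a gene with identical values everywhere fails the effect filter
  counts <- sc$counts
  counts["gene001", ] <- 5L
  mk2 <- findMarkers(counts, sc$clusters)
  expect_false(any(mk2$gene_id == "gene001"))
})

test_that("small clusters are excluded with a warning", {
  sc <- generateScCounts(304, nClusters = 3, cellsPerCluster = 30,
                         nGenes = 50, markersPerCluster = 2,
                         clusterIds = c("1", "2", "3"))
  labels <- sc$clusters
  labels[1:2] <- "tiny"
  labels[3:ncol(sc$counts)] <- rep(c("1", "2"),
                                   length.out = ncol(sc$counts) - 2)
  expect_warning(mk <- findMarkers(sc$counts, labels), "tiny")
  expect_false("tiny" %in% mk$cluster)
  expect_error(suppressWarnings(
    findMarkers(sc$counts[, 1:5], c("a", "a", "a", "b", "b"))),
    "at least 2 clusters")
})

test_that("candidate intersection counts lKC memberships and partitions", {
  mkRow <- function(gene, cluster, eff = 1)
    data.frame(gene_id = gene, cluster = cluster, effect = eff, p = 1e-9,
               p_adj = 1e-6, frac_in = .8, frac_out = .1, is_marker = TRUE)
  markers <- rbind(
    mkRow("gA", "1"), mkRow("gA", "2"), mkRow("gA", "6"),
    mkRow("gB", "1"), mkRow("gB", "7"),
    mkRow("gC", "6"),
    mkRow("gD", "3"),            # non-lKC cluster only
    mkRow("gE", "1", eff = -2),  # downregulated: not a positive marker
    mkRow("gZ", "2"))            # marker but not a target
  res <- intersectTargetsWithMarkers(c("gA", "gB", "gC", "gD", "gE"),
                                     markers)
  expect_setequal(res$candidates$gene_id, c("gA", "gB", "gC"))
  expect_equal(unname(res$buckets), c(1L, 1L, 1L))
  expect_equal(sum(res$buckets), nrow(res$candidates))
  expect_equal(res$candidates$n_clusters[res$candidates$gene_id == "gA"], 3L)
  expect_error(
    intersectTargetsWithMarkers("gA", markers,
                                lkcClusters = c("1", "2", "6", "9")), "9")
})

test_that("planted bucket membership is recovered exactly", {
  set.seed(71)
  lkc <- c("1", "2", "6", "7")
  nPer <- c(`3` = 4L, `2` = 10L, `1` = 20L)
  genes <- sprintf("t%03d", seq_len(sum(nPer)))
  memb <- c(lapply(seq_len(4), function(i) sample(lkc, 3)),
            lapply(seq_len(10), function(i) sample(lkc, 2)),
            lapply(seq_len(20), function(i) sample(lkc, 1)))
  markers <- do.call(rbind, lapply(seq_along(genes), function(i) {
    data.frame(gene_id = genes[i], cluster = memb[[i]], effect = 2,
               p = 1e-8, p_adj = 1e-5, frac_in = .9, frac_out = .05,
               is_marker = TRUE)
  }))
  ## pad with all four cluster ids so the namespace check passes
  markers <- rbind(markers,
                   data.frame(gene_id = "pad", cluster = lkc, effect = 0.5,
                              p = .5, p_adj = 1, frac_in = .2, frac_out = .2,
                              is_marker = FALSE))
  res <- intersectTargetsWithMarkers(genes, markers, lkcClusters = lkc)
  expect_equal(unname(res$buckets), c(4L, 10L, 20L))
  expect_equal(sum(res$buckets), length(genes))
})

test_that("reciprocal best hits follow the definition and its tie rules", {
  a2b <- data.frame(qseqid = "a1", sseqid = "b1", bitscore = 200,
                    evalue = 1e-50)
  b2a <- data.frame(qseqid = "b1", sseqid = "a1", bitscore = 190,
                    evalue = 1e-45)
  got <- reciprocalBestHits(a2b, b2a)
  expect_equal(got$id_a, "a1")
  expect_equal(got$score_b2a, 190)

  ## one-sided best: a1 -> b1 but b1 -> a2, so no pair for a1
  a2b2 <- rbind(a2b, data.frame(qseqid = "a2", sseqid = "b1",
                                bitscore = 150, evalue = 1e-30))
  b2a2 <- data.frame(qseqid = "b1", sseqid = c("a1", "a2"),
                     bitscore = c(100, 180), evalue = c(1e-10, 1e-40))
  oneSided <- reciprocalBestHits(a2b2, b2a2)
  expect_false("a1" %in% oneSided$id_a)
  expect_equal(oneSided$id_a, "a2")  # b1's best is a2, reciprocally

  ## duplicate (query, subject) rows: keep the best, with a warning
  dup <- rbind(a2b, data.frame(qseqid = "a1", sseqid = "b1", bitscore = 120,
                               evalue = 1e-20))
  expect_warning(gotDup <- reciprocalBestHits(dup, b2a), "duplicated")
  expect_equal(gotDup$score_a2b, 200)
})

test_that("RBH matches the definitional oracle and is role-symmetric", {
  set.seed(88)
  for (rep in 1:5) {
    nA <- 30; nB <- 30
    mkTab <- function(qs, ss) {
      n <- 120
      data.frame(qseqid = sample(qs, n, replace = TRUE),
                 sseqid = sample(ss, n, replace = TRUE),
                 bitscore = round(runif(n, 50, 400), 1),
                 evalue = signif(10^runif(n, -60, -3), 3))
    }
    a2b <- mkTab(sprintf("a%02d", 1:nA), sprintf("b%02d", 1:nB))
    b2a <- mkTab(sprintf("b%02d", 1:nB), sprintf("a%02d", 1:nA))
    dedup <- function(t) t[!duplicated(t[c("qseqid", "sseqid")]), ]
    a2b <- dedup(a2b[order(-a2b$bitscore), ])
    b2a <- dedup(b2a[order(-b2a$bitscore), ])
    got <- reciprocalBestHits(a2b, b2a)
    expect_equal(sort(paste(got$id_a, got$id_b)), oracleRBH(a2b, b2a))
    ## swapping table roles yields the same unordered pair set
    swapped <- reciprocalBestHits(b2a, a2b)
    expect_equal(sort(paste(got$id_a, got$id_b)),
                 sort(paste(swapped$id_b, swapped$id_a)))
  }
})
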