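test_that("q-value filtering keeps peaks beyond the -log10 threshold", {
  pk <- buildPeaks("c", c(100, 500, 900), c(200, 600, 1000),
                   qValue = c(2.0, 2.4, 35.7))
  kept <- filterPeaksByQ(pk, 0.005)  # -log10(0.005) ~ 2.301
  expect_length(kept, 2)
  expect_equal(mcols(kept)$qValue, c(2.4, 35.7))  # order preserved
  expect_length(filterPeaksByQ(pk, 1.0), 3)       # vacuous threshold
  expect_error(filterPeaksByQ(pk, 0), "qMax")
  expect_error(filterPeaksByQ(pk, 1.5), "qMax")
})

test_that("q filtering agrees with a direct-scale oracle on random peaks", {
  set.seed(21)
  q <- runif(500, 0, 12)
  pk <- buildPeaks("c", seq(1, by = 1000, length.out = 500),
                   seq(300, by = 1000, length.out = 500), qValue = q)
  for (qMax in c(0.005, 0.001, 0.2, 1)) {
    kept <- filterPeaksByQ(pk, qMax)
    oracle <- which(10^(-q) < qMax | qMax >= 1)  # back to the q scale
    expect_equal(mcols(kept)$name, mcols(pk)$name[oracle])
  }
})

test_that("identical replicate lists reconcile one-to-one at distance zero", {
  pk <- generateReplicatePeaks(3, c(ctg1 = 200000L), nTrue = 10,
                               nNoisePerRep = 0)$repA
  rec <- reconcileReplicates(pk, pk)
  expect_length(rec, length(pk))
  expect_true(all(anchorDistances(rec) == 0))
  expect_length(unmatchedPeaks(rec, "A"), 0)
})

test_that("the 1-kb reproducibility bound is inclusive", {
  a <- buildPeaks("c", 4900, 5100, qValue = 10, summit = 100)   # anchor 5000
  b <- buildPeaks("c", 5900, 6100, qValue = 12, summit = 100)   # anchor 6000
  expect_length(reconcileReplicates(a, b, maxDistance = 1000), 1)
  b2 <- buildPeaks("c", 5901, 6101, qValue = 12, summit = 100)  # anchor 6001
  expect_length(reconcileReplicates(a, b2, maxDistance = 1000), 0)
})

test_that("matching is exhaustively optimal, symmetric, and respects bounds", {
  set.seed(77)
  for (rep in 1:12) {
    n <- sample(4:12, 1); m <- sample(4:12, 1)
    aAnch <- sort(sample.int(20000, n)) + 5000L
    bAnch <- sort(sample.int(20000, m)) + 5000L
    a <- buildPeaks("c", aAnch - 100L, aAnch + 100L,
                    qValue = runif(n, 3, 30), summit = 100L,
                    name = sprintf("a%d", seq_len(n)))
    b <- buildPeaks("c", bAnch - 100L, bAnch + 100L,
                    qValue = runif(m, 3, 30), summit = 100L,
                    name = sprintf("b%d", seq_len(m)))
    rec <- reconcileReplicates(a, b, maxDistance = 1000)
    oracle <- bruteforceAssignment(aAnch, bAnch, 1000)
    expect_equal(length(rec), oracle$count)
    expect_equal(sum(anchorDistances(rec)), oracle$dist)
    expect_true(all(anchorDistances(rec) <= 1000))
    ## matched + unmatched partitions both inputs
    expect_equal(length(rec) + length(unmatchedPeaks(rec, "A")), n)
    expect_equal(length(rec) + length(unmatchedPeaks(rec, "B")), m)
    ## symmetry: swapping replicate roles gives the same pair set
    rec2 <- reconcileReplicates(b, a, maxDistance = 1000)
    pairs1 <- sort(paste(mcols(rec@peakA)$name, mcols(rec@peakB)$name))
    pairs2 <- sort(paste(mcols(rec2@peakB)$name, mcols(rec2@peakA)$name))
    expect_equal(pairs1, pairs2)
  }
})

test_that("the representative is the member with the larger -log10 q", {
  a <- buildPeaks("c", 4900, 5100, qValue = 10, summit = 100)
  b <- buildPeaks("c", 4950, 5150, qValue = 22, summit = 100)
  rec <- reconcileReplicates(a, b)
  expect_equal(mcols(representative(rec))$qValue, 22)
  expect_equal(mcols(representative(rec))$source, "B")
  ## center is the midpoint of the two anchors
  expect_equal(signalCenters(rec), as.integer(floor((5000 + 5050) / 2)))
})

test_that("planted true peaks are recovered with recall and precision 1", {
  pk <- generateReplicatePeaks(15, c(ctg1 = 400000L, ctg2 = 300000L),
                               nTrue = 20, nNoisePerRep = 10)
  rec <- reconcileReplicates(filterPeaksByQ(pk$repA, 0.005),
                             filterPeaksByQ(pk$repB, 0.005))
  nameA <- mcols(rec@peakA)$name
  nameB <- mcols(rec@peakB)$name
  truePairs <- grepl("^trueA", nameA) & grepl("^trueB", nameB) &
    sub("trueA_", "", nameA) == sub("trueB_", "", nameB)
  expect_equal(sum(truePairs), 20)  # recall 1
  expect_length(rec, 20)            # precision 1
})

test_that("peak windows have the documented extent and clip at boundaries", {
  genome <- generateGenome(5, c(ctg1 = 10000L))
  ## center at 0-based 5000 (1-based 5001), flank 150 -> 0-based [4850, 5150)
  rec <- buildSignalAt("ctg1", 5001)
  win <- extractPeakWindow(genome, rec, flank = 150)
  expect_equal(width(win), 300)
  expect_equal(mcols(win)$start, 4851)
  expect_false(mcols(win)$clipped)
  expect_equal(as.character(win[[1]]),
               toupper(as.character(Biostrings::subseq(genome[[1]], 4851, 5150))))

  recEdge <- buildSignalAt("ctg1", 101, halfWidth = 50)
  winEdge <- extractPeakWindow(genome, recEdge, flank = 150)
  expect_equal(width(winEdge), 250)  # min(2*flank, available)
  expect_true(mcols(winEdge)$clipped)

  expect_error(extractPeakWindow(genome, buildSignalAt("nope", 500)),
               "nope")
})

test_that("extracted windows relocate to their source coordinates", {
  genome <- generateGenome(6, c(ctg1 = 50000L))
  pk <- generateReplicatePeaks(6, c(ctg1 = 50000L), nTrue = 5,
                               nNoisePerRep = 0)
  rec <- reconcileReplicates(pk$repA, pk$repB)
  win <- extractPeakWindow(genome, rec)
  for (i in seq_along(win)) {
    hit <- Biostrings::matchPattern(win[[i]], genome[[1]])
    expect_true(mcols(win)$start[i] %in% start(hit))
  }
})
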