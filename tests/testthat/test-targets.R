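twoExonGene <- function() {
  buildGenes(list(list(
    id = "LOCg", contig = "ctg1", start = 20001, end = 24000, strand = "+",
    exons = list(c(20001, 21000), c(23001, 24000)))))
}

test_that("a signal centered in the intron is assigned with label Intron", {
  gm <- twoExonGene()
  rec <- buildSignalAt("ctg1", 22000)
  asg <- assignTargets(rec, gm)
  expect_equal(nrow(asg), 1)
  expect_equal(asg$gene_id, "LOCg")
  expect_equal(asg$position, "Intron")
  expect_equal(asg$distance, 0L)
})

test_that("the 10-kb window boundary is inclusive at exactly window bp", {
  gm <- twoExonGene()  # gene 0-based end = 24000
  ## signal starting exactly window bp past the gene end (0-based 34000)
  atBound <- buildSignalAt("ctg1", 34101, halfWidth = 100)  # 1-based 34001..
  expect_equal(start(representative(atBound)), 34001)
  asg <- assignTargets(atBound, gm, window = 10000)
  expect_equal(asg$gene_id, "LOCg")
  expect_equal(asg$position, "Downstream")
  expect_equal(asg$distance, 10000L)
  ## one base further: not assigned
  past <- buildSignalAt("ctg1", 34102, halfWidth = 100)
  asgPast <- assignTargets(past, gm, window = 10000)
  expect_true(is.na(asgPast$gene_id))
})

test_that("signals with no gene in range yield an explicit no-gene record", {
  gm <- twoExonGene()
  rec <- buildSignalAt("ctg1", 900000)
  asg <- assignTargets(rec, gm)
  expect_equal(nrow(asg), 1)
  expect_true(is.na(asg$gene_id))
  expect_true(is.na(asg$position))
})

test_that("assignment equals the exhaustive per-pair overlap oracle", {
  set.seed(33)
  contigs <- c(ctg1 = 1000000L, ctg2 = 800000L)
  gm <- generateGeneModels(34, contigs, n = 20)
  pk <- generateReplicatePeaks(35, contigs, nTrue = 50, nNoisePerRep = 0)
  rec <- reconcileReplicates(pk$repA, pk$repB)
  asg <- assignTargets(rec, gm, window = 10000)
  got <- sort(paste(asg$signal[!is.na(asg$gene_id)],
                    asg$gene_id[!is.na(asg$gene_id)]))
  oracle <- oracleTargetPairs(representative(rec), geneRanges(gm), 10000)
  want <- sort(paste(oracle$signal, geneIds(gm)[oracle$gene]))
  expect_equal(got, want)
})

test_that("position labels follow UTR > exon > intron and strand logic", {
  gm <- buildGenes(list(
    list(id = "LOCc", contig = "ctg1", start = 10001, end = 16000,
         strand = "+",
         exons = list(c(10001, 11000), c(12001, 13000), c(15001, 16000)),
         cds = list(c(10501, 11000), c(12001, 13000), c(15001, 15400))),
    list(id = "LOCn", contig = "ctg1", start = 40001, end = 44000,
         strand = "-", exons = list(c(40001, 41000), c(43001, 44000)))))
  ## center in exon 1 before the CDS start of a + strand gene -> 5'UTR
  expect_equal(classifyPosition(gm, "LOCc", 10300), "5'UTR")
  expect_equal(classifyPosition(gm, "LOCc", 15700), "3'UTR")
  expect_equal(classifyPosition(gm, "LOCc", 12500), "Exon")
  expect_equal(classifyPosition(gm, "LOCc", 11500), "Intron")
  ## 500 bp 5' of a minus-strand gene's TSS = higher genomic coordinate
  expect_equal(classifyPosition(gm, "LOCn", 44500), "Upstream")
  expect_equal(classifyPosition(gm, "LOCn", 39500), "Downstream")
  ## without CDS annotation, exonic centers are Exon, never UTR
  expect_equal(classifyPosition(gm, "LOCn", 40500), "Exon")
})

test_that("exactly one label is produced for every assigned pair", {
  set.seed(44)
  contigs <- c(ctg1 = 500000L)
  gm <- generateGeneModels(45, contigs, n = 15)
  pk <- generateReplicatePeaks(46, contigs, nTrue = 25, nNoisePerRep = 0)
  rec <- reconcileReplicates(pk$repA, pk$repB)
  asg <- assignTargets(rec, gm)
  lab <- asg$position[!is.na(asg$gene_id)]
  expect_true(all(lab %in% c("5'UTR", "3'UTR", "Exon", "Intron",
                             "Upstream", "Downstream")))
})

test_that("genes planted at known offsets are found iff within the window", {
  anchor <- 100000L
  offsets <- c(-15000L, -9000L, -500L, 3000L, 9999L, 10001L, 20000L)
  genes <- lapply(seq_along(offsets), function(i) {
    s <- anchor + offsets[i]
    list(id = sprintf("LOC%02d", i), contig = "ctg1",
         start = s, end = s + 400, strand = "+")
  })
  gm <- buildGenes(genes)
  rec <- buildSignalAt("ctg1", anchor, halfWidth = 0)
  asg <- assignTargets(rec, gm, window = 10000)
  ## planted in range: gene spans within 10 kb of the 1-bp signal
  inRange <- vapply(seq_along(offsets), function(i) {
    s <- anchor + offsets[i]; e <- s + 400
    max(s - anchor - 1, anchor - e - 1, 0) <= 10000
  }, logical(1))
  expect_setequal(asg$gene_id, sprintf("LOC%02d", which(inRange)))
  expect_equal(nrow(asg), sum(inRange))
})

test_that("signal report ranks by q, expands multi-gene rows, side-numbered", {
  gm <- buildGenes(list(
    list(id = "LOCa", contig = "ctg1", start = 9001, end = 12000,
         strand = "+"),
    list(id = "LOCb", contig = "ctg1", start = 13000, end = 15000,
         strand = "+"),
    list(id = "LOCc", contig = "ctg1", start = 50001, end = 52000,
         strand = "+"),
    list(id = "LOCd", contig = "ctg1", start = 90001, end = 92000,
         strand = "+")))
  mkSig <- function(center, q, fe) {
    pk <- buildPeaks("ctg1", center - 100, center + 100, qValue = q,
                     summit = 100, signalValue = fe)
    reconcileReplicates(pk, pk)
  }
  sig <- list(mkSig(10500, 17.7, 5.24), mkSig(51000, 35.7, 6.45),
              mkSig(91000, 23.3, 5.64))
  recAll <- new("ReconciledPeaks",
                representative = do.call(c, lapply(sig, representative)),
                peakA = do.call(c, lapply(sig, slot, "peakA")),
                peakB = do.call(c, lapply(sig, slot, "peakB")),
                unmatchedA = GRanges(), unmatchedB = GRanges(),
                maxDistance = 1000)
  asg <- assignTargets(recAll, gm)
  rpt <- rankSignalReport(asg, topN = 20)
  ## q order 35.7 > 23.3 > 17.7
  expect_equal(rpt$neg_log10_q[!is.na(rpt$neg_log10_q)], c(35.7, 23.3, 17.7))
  ## the 17.7 signal has two genes within 10 kb -> side-numbered rows
  expect_true(all(c("3-1", "3-2") %in% rpt$gene_no))
  expect_error(rankSignalReport(asg, topN = 0), "topN")

  single <- rankSignalReport(assignTargets(sig[[2]], gm), topN = 20)
  expect_equal(nrow(single), 1)
})

test_that("signal report ordering matches an independent sort oracle", {
  set.seed(55)
  n <- 100
  centers <- seq(5000, by = 5000, length.out = n)
  q <- round(runif(n, 3, 40), 3)
  fe <- round(runif(n, 2, 9), 3)
  pk <- buildPeaks("ctg1", centers - 100, centers + 100, qValue = q,
                   summit = 100, signalValue = fe)
  rec <- reconcileReplicates(pk, pk)
  asg <- assignTargets(rec, buildGenes(list(
    list(id = "LOCfar", contig = "ctg9", start = 1, end = 10,
         strand = "+"))))
  rpt <- rankSignalReport(asg, topN = n)
  perm <- order(-q, -fe, centers)
  expect_equal(rpt$neg_log10_q, q[perm])
})

test_that("target set comparison reproduces the printed arithmetic", {
  ## |b| = 263 sharing 125 with a -> 138 b-specific, 52%
  a <- c(paste0("s", 1:125), paste0("a", 1:300))
  b <- c(paste0("s", 1:125), paste0("b", 1:138))
  cmp <- compareTargetSets(a, b)
  expect_length(specificIds(cmp, "B"), 138)
  expect_equal(unname(fractionsPercent(cmp)["b_specific"]), 52)

  d <- compareTargetSets(letters[1:4], LETTERS[1:6])
  expect_length(commonIds(d), 0)
  expect_equal(unname(fractionsPercent(d)[c("a_specific", "b_specific")]),
               c(100, 100))
})

test_that("set comparison matches brute-force membership on random sets", {
  set.seed(66)
  for (i in 1:20) {
    a <- unique(sample(sprintf("g%03d", 1:150), sample(10:80, 1)))
    b <- unique(sample(sprintf("g%03d", 1:150), sample(10:80, 1)))
    cmp <- compareTargetSets(a, b)
    expect_setequal(commonIds(cmp), a[vapply(a, function(x) x %in% b,
                                             logical(1))])
    expect_setequal(specificIds(cmp, "A"),
                    a[vapply(a, function(x) !x %in% b, logical(1))])
    expect_equal(length(specificIds(cmp, "A")) + length(commonIds(cmp)),
                 length(a))
  }
})
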