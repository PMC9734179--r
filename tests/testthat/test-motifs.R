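test_that("overlap-allowed counting reproduces the worked examples", {
  expect_equal(countOverlapping("GAGA", "GAGA"), 1L)
  expect_equal(countOverlapping("GAGA", "GAG"), 1L)
  expect_equal(countOverlapping("GAGAG", "GAGA"), 1L)
  expect_equal(countOverlapping("GAGAG", "GAG"), 2L)
  expect_equal(countOverlapping("GAGAGA", "GAGA"), 2L)
  expect_equal(countOverlapping("", "GAG"), 0L)
  expect_error(countOverlapping("GAGA", ""), "non-empty")
})

test_that("counting equals the naive oracle and Biostrings on random input", {
  set.seed(101)
  for (i in 1:300) {
    s <- randomDnaSeq(sample(10:80, 1), c("A", "C", "G", "T", "N"))
    motif <- randomDnaSeq(sample(2:5, 1))
    mine <- countOverlapping(s, motif)
    expect_equal(mine, naiveCountOverlapping(s, motif))
    expect_equal(mine, Biostrings::countPattern(motif,
                                                Biostrings::DNAString(s)))
    ## every GAGA starts a GAG
    expect_gte(countOverlapping(s, "GAG"), countOverlapping(s, "GAGA"))
  }
})

test_that("motif specs expand the optional base and reject bad codes", {
  expect_setequal(expandMotif(motifSpec("m3", "AT(C)TTTGTA")),
                  c("ATCTTTGTA", "ATTTTGTA"))
  expect_equal(expandMotif(motifSpec("gaga", "GAGA")), "GAGA")
  expect_error(motifSpec("bad", "AXGT"), "IUPAC")
  expect_error(motifSpec("bad", "A(C)(G)T"), "optional")
})

test_that("scanning matches expansions, IUPAC codes, and both strands", {
  res <- scanMotif("ATCTTTGTAATTTTGTA", motifSpec("m3", "AT(C)TTTGTA"))
  expect_equal(res$count, 2)
  expect_equal(res$positions$start, c(1, 10))

  self <- scanMotif("GAAATTTT", motifSpec("m2", "GAAATTTT"))
  expect_equal(self$count, 1)
  expect_equal(self$positions$start, 1)

  ## IUPAC: R = A/G; N in the sequence never matches
  iu <- scanMotif("CATCGTNT", motifSpec("iu", "RT"))
  expect_equal(iu$positions$start, c(2, 5))

  ## palindromic expansion: counted once per strand
  pal <- scanMotif("ATAT", motifSpec("pal", "AT"), countBothStrands = TRUE)
  expect_equal(pal$count, 4)
  expect_setequal(unique(pal$positions$strand), c("+", "-"))

  ## enabling both strands never decreases the count
  set.seed(7)
  for (i in 1:25) {
    s <- randomDnaSeq(60)
    one <- scanMotif(s, motifSpec("g", "GAGA"))$count
    two <- scanMotif(s, motifSpec("g", "GAGA"), countBothStrands = TRUE)$count
    expect_gte(two, one)
  }
})

test_that("upstream windows are strand-aware, oriented, and clipped", {
  genome <- generateGenome(12, c(ctg1 = 10000L))
  gm <- buildGenes(list(
    ## + strand, TSS 0-based 5000 (1-based 5001): window = bases [3000,5000)
    list(id = "plus", contig = "ctg1", start = 5001, end = 6000,
         strand = "+"),
    ## - strand, TSS 0-based 5000 = span.end - 1 (1-based end 5001):
    ## window = revcomp of bases [5001, 7001)
    list(id = "minus", contig = "ctg1", start = 4001, end = 5001,
         strand = "-"),
    list(id = "edge", contig = "ctg1", start = 501, end = 1500,
         strand = "+")))
  up <- extractUpstream(gm, genome, length = 2000)
  expect_equal(as.character(up[["plus"]]),
               toupper(as.character(Biostrings::subseq(genome[[1]], 3001, 5000))))
  expect_equal(as.character(up[["minus"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::subseq(genome[[1]], 5002, 7001))))
  ## TSS at 0-based 500 -> 500 available bases, clip flag set
  expect_equal(mcols(up)["edge", "effective_length"], 500L)
  expect_true(mcols(up)["edge", "clipped"])
  expect_equal(width(up["edge"]), 500)

  expect_error(extractUpstream(gm, genome[0], 2000), "contig")
})

test_that("upstream windows back-project onto their genomic interval", {
  genome <- generateGenome(13, c(ctg1 = 30000L))
  gm <- generateGeneModels(14, c(ctg1 = 30000L), n = 5)
  up <- extractUpstream(gm, genome, length = 1000)
  info <- mcols(up)
  for (i in seq_along(up)) {
    if (info$effective_length[i] == 0) next
    x <- up[[i]]
    if (info$strand[i] == "-") x <- Biostrings::reverseComplement(x)
    hit <- Biostrings::matchPattern(x, genome[[info$contig[i]]])
    expect_true(info$start[i] %in% start(hit))
  }
})

test_that("species motif table recovers planted counts and flags absences", {
  ## all-N contig: no background, planted counts are exact
  blank <- Biostrings::DNAStringSet(c(ctgN = paste(rep("N", 30000),
                                                   collapse = "")))
  gm <- buildGenes(list(list(id = "hom1", contig = "ctgN", start = 20001,
                             end = 22000, strand = "+")))
  planted <- plantUpstreamMotifs(blank, gm, "hom1", gagaN = 37, gagN = 75,
                                 window = 2000, seed = 3)
  expect_equal(planted$truth$gaga, 37L)
  expect_equal(planted$truth$gag, 112L)  # 37 GAGA each contain one GAG
  up <- extractUpstream(gm, planted$genome, length = 2000)
  mcols(up)$subject <- "species1"
  tbl <- speciesMotifTable(up, windows = c(2000, 10000))
  expect_equal(tbl$count[tbl$window_length == 2000 & tbl$motif == "GAGA"], 37L)
  expect_equal(tbl$count[tbl$window_length == 2000 & tbl$motif == "GAG"], 112L)
  ## no 10-kb record was provided: absent, not zero
  expect_true(all(is.na(tbl$count[tbl$window_length == 10000])))
  expect_true(all(!tbl$present[tbl$window_length == 10000]))
  ## all-N window counts zero
  upN <- extractUpstream(gm, blank, length = 2000)
  mcols(upN)$subject <- "blank"
  tblN <- speciesMotifTable(upN, windows = 2000)
  expect_true(all(tblN$count == 0L))
})

test_that("planted motif counts equal an independent recount anywhere", {
  genome <- generateGenome(15, c(ctg1 = 30000L))
  gm <- buildGenes(list(list(id = "g1", contig = "ctg1", start = 20001,
                             end = 22000, strand = "-")))
  res <- plantUpstreamMotifs(genome, gm, "g1", gagaN = 12, gagN = 20,
                             window = 2000, seed = 9)
  up <- extractUpstream(gm, res$genome, length = 2000)
  expect_equal(naiveCountOverlapping(as.character(up[[1]]), "GAGA"),
               res$truth$gaga)
  expect_equal(naiveCountOverlapping(as.character(up[[1]]), "GAG"),
               res$truth$gag)
  expect_gte(res$truth$gaga, 12L)  # background can only add occurrences
  expect_gte(res$truth$gag, 32L)
  ## infeasible request is rejected
  expect_error(plantUpstreamMotifs(genome, gm, "g1", gagaN = 300, gagN = 300,
                                   window = 2000), "infeasible")
})
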