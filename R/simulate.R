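## Seeded generators for every input the pipeline consumes, with planted
## ground truth. All generators are pure functions of (seed, parameters):
## the RNG state is scoped with withr::with_seed, so the same call yields
## byte-identical output and never disturbs the caller's RNG.

#' Generate a random genome
#'
#' I.i.d. nucleotides at a fixed GC content; a pure function of the seed.
#'
#' @param seed integer seed.
#' @param contigLengths named integer vector of contig lengths in bp.
#' @param gc GC content in (0, 1), default 0.35 (AT-rich, insect-like).
#' @return \code{DNAStringSet} named by contig.
#' @export
generateGenome <- function(seed, contigLengths, gc = 0.35) {
  if (!is.numeric(gc) || length(gc) != 1L || is.na(gc) || gc <= 0 || gc >= 1)
    stopf("gc must lie strictly between 0 and 1")
  if (is.null(names(contigLengths)))
    names(contigLengths) <- paste0("ctg", seq_along(contigLengths))
  withr::with_seed(seed, {
    seqs <- vapply(contigLengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    }, character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- names(contigLengths)
    out
  })
}

#' Generate a random gene catalog
#'
#' Places non-overlapping genes with 1-4 exons on random strands; a subset
#' gets a CDS (leaving UTR ends) so UTR/exon/intron classification is
#' exercised. Gene starts can be pinned with \code{at} to plant genes at
#' known offsets from peaks.
#'
#' @param seed integer seed.
#' @param contigLengths named integer vector of contig lengths.
#' @param n number of genes.
#' @param widthRange gene span range in bp (default 1000-4000).
#' @param gap minimum gap between consecutive genes (default 2000).
#' @param cdsFraction fraction of genes given a CDS (default 0.5).
#' @param at optional \code{GRanges} of gene spans (with strand) to use
#'   verbatim instead of random placement; \code{n} is then ignored.
#' @return a \code{\link{GeneModels}} object.
#' @export
generateGeneModels <- function(seed, contigLengths, n = 20,
                               widthRange = c(1000, 4000), gap = 2000,
                               cdsFraction = 0.5, at = NULL) {
  if (is.null(names(contigLengths)))
    names(contigLengths) <- paste0("ctg", seq_along(contigLengths))
  withr::with_seed(seed, {
    if (is.null(at)) {
      ctgV <- character(); sV <- integer(); eV <- integer()
      stdV <- character()
      ctgs <- rep(names(contigLengths), length.out = n)
      for (ctg in unique(ctgs)) {
        k <- sum(ctgs == ctg)
        L <- contigLengths[[ctg]]
        pos <- 1L
        for (i in seq_len(k)) {
          w <- sample(widthRange[1]:widthRange[2], 1L)
          s <- pos + sample(gap:(2L * gap), 1L)
          if (s + w - 1L > L - gap) break
          ctgV <- c(ctgV, ctg); sV <- c(sV, s); eV <- c(eV, s + w - 1L)
          stdV <- c(stdV, sample(c("+", "-"), 1L))
          pos <- s + w - 1L
        }
      }
      spans <- GRanges(ctgV, IRanges(sV, eV), strand = stdV)
    } else spans <- at
    ids <- paste0("LOC", 100000L + seq_along(spans))
    exons <- GRangesList(lapply(seq_along(spans), function(i) {
      g <- spans[i]
      nEx <- sample(1:4, 1L)
      if (nEx == 1L) return(granges(g))
      ## cut the span into 2*nEx-1 alternating exon/intron segments
      w <- width(g)
      cuts <- sort(sample(seq_len(w - 1L), 2L * nEx - 2L))
      bounds <- c(0L, cuts, w)
      segS <- start(g) + bounds[-length(bounds)]
      segE <- start(g) + bounds[-1L] - 1L
      keep <- seq(1L, 2L * nEx - 1L, by = 2L)
      GRanges(seqnames(g), IRanges(segS[keep], segE[keep]),
              strand = strand(g))
    }))
    names(exons) <- ids
    hasCds <- stats::runif(length(spans)) < cdsFraction
    cds <- list()
    for (i in which(hasCds)) {
      e <- exons[[i]]
      exTotal <- sum(width(e))
      if (exTotal < 60L) next
      ## CDS: trim ~15% off each end of the exonic extent
      trim <- max(10L, as.integer(0.15 * exTotal))
      cdsSpan <- GRanges(seqnames(spans[i]),
                         IRanges(start(spans[i]) + trim,
                                 end(spans[i]) - trim))
      ov <- GenomicRanges::intersect(e, cdsSpan, ignore.strand = TRUE)
      if (length(ov)) cds[[ids[i]]] <- ov
    }
    g <- granges(spans)
    mcols(g) <- DataFrame(
      gene_id = ids,
      description = paste("synthetic gene", seq_along(spans)),
      biotype = ifelse(ids %in% names(cds), "protein_coding", "other"))
    GeneModels(g, exons, GRangesList(cds))
  })
}

#' Plant GA-rich motifs in a gene's upstream window
#'
#' Writes \code{gagaN} GAGA and \code{gagN} standalone GAG placements at
#' random non-adjacent offsets in the \code{window} bases 5' of the gene's
#' TSS (gene orientation). Because each GAGA placement itself contains a
#' GAG, and the background can contain occurrences of its own, the realised
#' overlap-allowed counts are recomputed on the final window with
#' \code{\link{countOverlapping}} and recorded as the truth.
#'
#' @param genome \code{DNAStringSet}.
#' @param genes a \code{\link{GeneModels}} object.
#' @param geneId gene whose upstream window is modified.
#' @param gagaN,gagN number of GAGA / standalone GAG placements.
#' @param window upstream window length in bp (default 2000).
#' @param seed integer seed.
#' @return list with \code{genome} (modified copy) and \code{truth}
#'   (realised \code{gaga}/\code{gag} counts, requested numbers, window).
#' @export
plantUpstreamMotifs <- function(genome, genes, geneId, gagaN, gagN,
                                window = 2000, seed = 1L) {
  if (gagaN < 0 || gagN < 0) stopf("motif counts must be nonnegative")
  nPlace <- gagaN + gagN
  needed <- 4L * gagaN + 3L * gagN + max(0L, nPlace - 1L)
  if (needed > window)
    stopf("infeasible request: %d GAGA + %d GAG need %d bp, window is %d",
          gagaN, gagN, needed, window)
  up <- extractUpstream(genes, genome, length = window, geneId = geneId)
  info <- mcols(up)
  if (info$effective_length < window)
    stopf("upstream window of %s is clipped to %d bp; cannot plant %d bp",
          geneId, info$effective_length, window)
  seqChr <- as.character(up[[1L]])
  withr::with_seed(seed, {
    if (nPlace > 0L) {
      motifs <- sample(c(rep("GAGA", gagaN), rep("GAG", gagN)))
      lens <- nchar(motifs)
      slack <- window - sum(lens) - (nPlace - 1L)
      extra <- tabulate(sample.int(nPlace + 1L, slack, replace = TRUE),
                        nPlace + 1L)
      gaps <- extra
      if (nPlace > 1L) gaps[2:nPlace] <- gaps[2:nPlace] + 1L
      pos <- cumsum(gaps[seq_len(nPlace)] + c(0L, lens[-nPlace])) + 1L
      for (i in seq_len(nPlace)) {
        substr(seqChr, pos[i], pos[i] + lens[i] - 1L) <- motifs[i]
      }
    }
  })
  ## write the modified window back in genomic orientation
  genomic <- if (info$strand == "-") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqChr)))
  } else seqChr
  ctgSeq <- as.character(genome[[info$contig]])
  substr(ctgSeq, info$start, info$end) <- genomic
  out <- genome
  out[[info$contig]] <- Biostrings::DNAString(ctgSeq)
  truth <- list(gaga = countOverlapping(seqChr, "GAGA"),
                gag = countOverlapping(seqChr, "GAG"),
                requested_gaga = gagaN, requested_gag = gagN,
                window = window, gene_id = geneId)
  list(genome = out, truth = truth)
}

## sample positions on contigs keeping a minimum separation from a set of
## occupied positions (and from each other)
.samplePositions <- function(contigLengths, n, minSep, margin,
                             occupied = NULL) {
  ctgNames <- names(contigLengths)
  pos <- data.frame(contig = character(), at = integer())
  tries <- 0L
  while (nrow(pos) < n) {
    tries <- tries + 1L
    if (tries > 10000L)
      stopf("could not place %d positions with separation %d; contigs too small",
            n, minSep)
    ctg <- sample(ctgNames, 1L)
    at <- sample(seq(margin, contigLengths[[ctg]] - margin), 1L)
    near <- function(d) any(d$contig == ctg & abs(d$at - at) < minSep)
    if ((!is.null(occupied) && near(occupied)) || near(pos)) next
    pos <- rbind(pos, data.frame(contig = ctg, at = at))
  }
  pos
}

#' Generate two replicate peak sets with planted truth
#'
#' Plants \code{nTrue} true binding sites, each appearing in both replicates
#' with independently jittered summits (|shift| capped at 500 bp so pairs
#' stay within the 1-kb reproducibility bound), plus \code{nNoisePerRep}
#' replicate-specific noise peaks placed at least 2,500 bp from every true
#' anchor and from each other, so reconciliation recovery is exact. Score
#' columns are internally consistent (\eqn{-\log_{10} q \le -\log_{10} p})
#' and rounded to 5 decimals, as a peak caller would print them.
#'
#' @param seed integer seed.
#' @param contigLengths named integer vector of contig lengths.
#' @param nTrue number of true peaks (default 20).
#' @param jitterSd summit jitter standard deviation in bp (default 100).
#' @param nNoisePerRep noise peaks per replicate (default 10).
#' @param trueAnchors optional \code{data.frame(contig, at)} of true summit
#'   positions (sampled at >= 5 kb separation when \code{NULL}).
#' @return list with \code{repA}, \code{repB} (\code{GRanges} with
#'   narrowPeak metadata) and \code{truth} (anchors, per-replicate jitters,
#'   peak names).
#' @export
generateReplicatePeaks <- function(seed, contigLengths, nTrue = 20,
                                   jitterSd = 100, nNoisePerRep = 10,
                                   trueAnchors = NULL) {
  withr::with_seed(seed, {
    if (is.null(names(contigLengths)))
      names(contigLengths) <- paste0("ctg", seq_along(contigLengths))
    if (is.null(trueAnchors))
      trueAnchors <- .samplePositions(contigLengths, nTrue, 5000L, 2000L)
    nTrue <- nrow(trueAnchors)
    noise <- .samplePositions(contigLengths, 2L * nNoisePerRep, 2500L, 2000L,
                              occupied = trueAnchors)
    jitterOne <- function() {
      j <- round(stats::rnorm(nTrue, 0, jitterSd))
      while (any(abs(j) > 500)) {
        bad <- abs(j) > 500
        j[bad] <- round(stats::rnorm(sum(bad), 0, jitterSd))
      }
      as.integer(j)
    }
    jA <- jitterOne(); jB <- jitterOne()
    mkPeaks <- function(contig, anchor, prefix) {
      contig <- factor(contig, levels = names(contigLengths))
      n <- length(anchor)
      if (n == 0L) {
        gr <- GRanges(seqnames = contig, ranges = IRanges())
        mcols(gr) <- DataFrame(name = character(), score = integer(),
                               signalValue = numeric(), pValue = numeric(),
                               qValue = numeric(), peak = integer())
        return(gr)
      }
      halfL <- sample(120:220, n, replace = TRUE)
      halfR <- sample(120:220, n, replace = TRUE)
      s <- anchor - halfL; e <- anchor + halfR
      q <- round(stats::runif(n, 5, 40), 5)
      p <- round(q + stats::runif(n, 0.1, 3), 5)
      gr <- GRanges(contig, IRanges(s, e))
      mcols(gr) <- DataFrame(
        name = paste0(prefix, "_", seq_len(n)),
        score = as.integer(pmin(1000, round(10 * q))),
        signalValue = round(stats::runif(n, 3, 9), 5),
        pValue = p, qValue = q,
        peak = as.integer(anchor - s))  # 0-based offset from chromStart
      gr
    }
    noiseA <- noise[seq_len(nNoisePerRep), , drop = FALSE]
    noiseB <- noise[nNoisePerRep + seq_len(nNoisePerRep), , drop = FALSE]
    repA <- c(mkPeaks(trueAnchors$contig, trueAnchors$at + jA, "trueA"),
              mkPeaks(noiseA$contig, noiseA$at, "noiseA"))
    repB <- c(mkPeaks(trueAnchors$contig, trueAnchors$at + jB, "trueB"),
              mkPeaks(noiseB$contig, noiseB$at, "noiseB"))
    list(repA = repA, repB = repB,
         truth = list(anchors = trueAnchors, jitterA = jA, jitterB = jB,
                      trueNamesA = paste0("trueA_", seq_len(nTrue)),
                      trueNamesB = paste0("trueB_", seq_len(nTrue)),
                      seed = seed))
  })
}

#' Generate a single-cell count matrix with planted cluster markers
#'
#' Negative-binomial counts (gene-wise base means, common dispersion) for
#' \code{nClusters} clusters of \code{cellsPerCluster} cells each;
#' \code{markersPerCluster} disjoint genes per cluster have their mean
#' multiplied by \code{fold} in that cluster only. Truth records the planted
#' (gene, cluster) pairs.
#'
#' @param seed integer seed.
#' @param nClusters,cellsPerCluster,nGenes matrix dimensions.
#' @param markersPerCluster planted marker genes per cluster.
#' @param fold marker fold change (> 1; use 1 for a global null).
#' @param nbDispersion negative-binomial dispersion (> 0; variance =
#'   mu + dispersion * mu^2).
#' @param clusterIds cluster labels (default \code{"1".."nClusters"}).
#' @return list with \code{counts} (genes x cells), \code{clusters} (label
#'   per cell), \code{truth} (\code{data.frame(gene_id, cluster)}).
#' @export
generateScCounts <- function(seed, nClusters = 4, cellsPerCluster = 100,
                             nGenes = 200, markersPerCluster = 5, fold = 8,
                             nbDispersion = 0.5,
                             clusterIds = as.character(seq_len(nClusters))) {
  if (nbDispersion <= 0) stopf("nbDispersion must be positive")
  if (fold < 1) stopf("marker fold must be >= 1")
  if (length(clusterIds) != nClusters)
    stopf("need %d cluster ids", nClusters)
  withr::with_seed(seed, {
    nCells <- nClusters * cellsPerCluster
    clusters <- rep(clusterIds, each = cellsPerCluster)
    baseMean <- exp(stats::rnorm(nGenes, log(2), 0.6))
    geneIdsV <- sprintf("gene%03d", seq_len(nGenes))
    planted <- if (fold > 1 && markersPerCluster > 0) {
      idx <- sample.int(nGenes, nClusters * markersPerCluster)
      data.frame(gene_id = geneIdsV[idx],
                 cluster = rep(clusterIds, each = markersPerCluster),
                 stringsAsFactors = FALSE)
    } else data.frame(gene_id = character(), cluster = character())
    mu <- matrix(baseMean, nGenes, nCells)
    for (r in seq_len(nrow(planted))) {
      gi <- match(planted$gene_id[r], geneIdsV)
      mu[gi, clusters == planted$cluster[r]] <-
        mu[gi, clusters == planted$cluster[r]] * fold
    }
    counts <- matrix(stats::rnbinom(nGenes * nCells, mu = mu,
                                    size = 1 / nbDispersion),
                     nGenes, nCells,
                     dimnames = list(geneIdsV,
                                     sprintf("cell%04d", seq_len(nCells))))
    list(counts = counts, clusters = clusters, truth = planted)
  })
}

#' Generate reciprocal hit tables with planted mutual-best pairs
#'
#' Builds two BLAST-outfmt-6-like tables. Planted pairs get dominant
#' bitscores in both directions; every other query's best hit is arranged
#' asymmetrically (its best subject's own best points elsewhere), so the
#' reciprocal-best-hit set equals exactly the planted pairs.
#'
#' @param seed integer seed.
#' @param nA,nB number of query ids on either side.
#' @param nTruePairs planted ortholog pairs (<= min(nA, nB)).
#' @return list with \code{a2b}, \code{b2a} (\code{data.frame}s with
#'   \code{qseqid}, \code{sseqid}, \code{bitscore}, \code{evalue}) and
#'   \code{truth} (\code{data.frame(id_a, id_b)}).
#' @export
generateHitTables <- function(seed, nA = 30, nB = 30, nTruePairs = 10) {
  if (nTruePairs > min(nA, nB))
    stopf("nTruePairs must not exceed min(nA, nB)")
  withr::with_seed(seed, {
    idsA <- sprintf("A%03d", seq_len(nA))
    idsB <- sprintf("B%03d", seq_len(nB))
    pairA <- sample(idsA, nTruePairs)
    pairB <- sample(idsB, nTruePairs)
    rows <- function(q, s, lo, hi) {
      data.frame(qseqid = q, sseqid = s,
                 bitscore = round(stats::runif(length(q), lo, hi), 1),
                 evalue = signif(10^stats::runif(length(q), -50, -5), 3),
                 stringsAsFactors = FALSE)
    }
    a2b <- rows(pairA, pairB, 200, 400)
    b2a <- rows(pairB, pairA, 200, 400)
    freeA <- setdiff(idsA, pairA); freeB <- setdiff(idsB, pairB)
    ## designated (asymmetric) best hits for unplanted queries
    bestFor <- function(qs, subjects, shift) {
      if (!length(qs) || !length(subjects)) return(NULL)
      sIdx <- (seq_along(qs) - 1L + shift) %% length(subjects) + 1L
      rows(qs, subjects[sIdx], 100, 150)
    }
    if (nTruePairs > 0) {
      ## unplanted queries point at planted subjects, whose own best is
      ## their planted partner
      a2b <- rbind(a2b, bestFor(freeA, pairB, 0L))
      b2a <- rbind(b2a, bestFor(freeB, pairA, 0L))
    } else if (length(freeA) && length(freeB)) {
      a2b <- rbind(a2b, bestFor(freeA, freeB, 0L))
      b2a <- rbind(b2a, bestFor(freeB, freeA, 1L))
    }
    ## low-score decoy noise for a random subset of queries (never
    ## duplicating an existing (query, subject) row)
    decoy <- function(tab, qs, subjects) {
      k <- max(1L, length(qs) %/% 2L)
      dq <- sample(qs, k)
      d <- rows(dq, sample(subjects, k, replace = TRUE), 50, 95)
      d <- d[!paste(d$qseqid, d$sseqid) %in%
               paste(tab$qseqid, tab$sseqid), , drop = FALSE]
      rbind(tab, d)
    }
    a2b <- decoy(a2b, idsA, idsB)
    b2a <- decoy(b2a, idsB, idsA)
    ## enforce the contract definitionally: compute each side's best hit and
    ## drop the b-side hits of any accidental non-planted mutual pair
    bestMap <- function(tab) {
      tab <- tab[order(tab$qseqid, -tab$bitscore, tab$evalue, tab$sseqid), ]
      tab <- tab[!duplicated(tab$qseqid), ]
      stats::setNames(tab$sseqid, tab$qseqid)
    }
    repeat {
      bA <- bestMap(a2b); bB <- bestMap(b2a)
      mutual <- names(bA)[!is.na(bB[bA]) & bB[bA] == names(bA)]
      spurious <- setdiff(mutual, pairA)
      if (!length(spurious)) break
      b2a <- b2a[!b2a$qseqid %in% bA[spurious], , drop = FALSE]
    }
    a2b <- a2b[order(a2b$qseqid, -a2b$bitscore), ]
    b2a <- b2a[order(b2a$qseqid, -b2a$bitscore), ]
    rownames(a2b) <- rownames(b2a) <- NULL
    list(a2b = a2b, b2a = b2a,
         truth = data.frame(id_a = sort(pairA),
                            id_b = pairB[order(pairA)],
                            stringsAsFactors = FALSE))
  })
}

#' @rdname generateHitTables
#' @param tab a hit table \code{data.frame}.
#' @param path output TSV path.
#' @export
writeHitTable <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
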