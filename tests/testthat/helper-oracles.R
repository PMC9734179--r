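## Independent oracles and small fixture builders used across the suite.
## Oracles deliberately use naive algorithms (per-base loops, bitmask DP,
## definitional scans) so they share no code path with the implementation.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

## every-start-position motif counter (explicit loop)
naiveCountOverlapping <- function(seq, motif) {
  n <- nchar(seq); k <- nchar(motif)
  if (n < k) return(0L)
  cnt <- 0L
  for (i in seq_len(n - k + 1L)) {
    if (substr(seq, i, i + k - 1L) == motif) cnt <- cnt + 1L
  }
  cnt
}

randomDnaSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## exact maximum-cardinality min-total-distance assignment by bitmask DP
## over the B side (independent of the package's non-crossing DP)
bruteforceAssignment <- function(a, b, maxD) {
  n <- length(a); m <- length(b)
  stopifnot(m <= 16)
  nMask <- bitwShiftL(1L, m)
  INF <- 1e18
  ## best[mask] after considering a[1..i]: c(count, dist), count maximised,
  ## dist minimised
  bestCnt <- rep(0L, nMask); bestDst <- rep(0, nMask)
  for (i in seq_len(n)) {
    newCnt <- bestCnt; newDst <- bestDst
    for (mask in 0:(nMask - 1L)) {
      for (j in seq_len(m)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) > 0L) next
        d <- abs(a[i] - b[j])
        if (d > maxD) next
        c2 <- bestCnt[mask + 1L] + 1L
        d2 <- bestDst[mask + 1L] + d
        k <- bitwOr(mask, bit) + 1L
        if (c2 > newCnt[k] || (c2 == newCnt[k] && d2 < newDst[k])) {
          newCnt[k] <- c2; newDst[k] <- d2
        }
      }
    }
    bestCnt <- newCnt; bestDst <- newDst
  }
  best <- 1L
  for (k in seq_len(nMask)) {
    if (bestCnt[k] > bestCnt[best] ||
        (bestCnt[k] == bestCnt[best] && bestDst[k] < bestDst[best]))
      best <- k
  }
  list(count = bestCnt[best], dist = bestDst[best])
}

## definitional all-pairs (signal, gene) qualification oracle
oracleTargetPairs <- function(signals, genes, window) {
  out <- list()
  for (i in seq_along(signals)) {
    for (j in seq_along(genes)) {
      if (as.character(seqnames(signals))[i] !=
          as.character(seqnames(genes))[j]) next
      gap <- max(start(signals)[i] - end(genes)[j] - 1L,
                 start(genes)[j] - end(signals)[i] - 1L, 0L)
      if (gap <= window)
        out[[length(out) + 1L]] <- c(signal = i, gene = j)
    }
  }
  if (!length(out)) return(data.frame(signal = integer(), gene = integer()))
  as.data.frame(do.call(rbind, out))
}

## definitional reciprocal-best-hit oracle
oracleRBH <- function(a2b, b2a) {
  bestOf <- function(tab, q) {
    rows <- tab[tab$qseqid == q, , drop = FALSE]
    if (!nrow(rows)) return(NA_character_)
    rows <- rows[order(-rows$bitscore, rows$evalue, rows$sseqid), ,
                 drop = FALSE]
    rows$sseqid[1L]
  }
  pairs <- character()
  for (q in unique(a2b$qseqid)) {
    s <- bestOf(a2b, q)
    if (!is.na(s) && identical(bestOf(b2a, s), q))
      pairs <- c(pairs, paste(q, s))
  }
  sort(pairs)
}

## quick single/multi gene GeneModels builder:
## genes: list of list(id, contig, start, end, strand, exons = list(c(s, e)),
##                     cds = list(c(s, e)) or NULL)
buildGenes <- function(genes) {
  spans <- GRanges(
    vapply(genes, `[[`, character(1), "contig"),
    IRanges(vapply(genes, `[[`, numeric(1), "start"),
            vapply(genes, `[[`, numeric(1), "end")),
    strand = vapply(genes, `[[`, character(1), "strand"))
  ids <- vapply(genes, `[[`, character(1), "id")
  mcols(spans) <- S4Vectors::DataFrame(
    gene_id = ids, description = paste("gene", ids),
    biotype = vapply(genes, function(g)
      if (is.null(g$cds)) "other" else "protein_coding", character(1)))
  exons <- GRangesList(lapply(genes, function(g) {
    ex <- if (is.null(g$exons)) list(c(g$start, g$end)) else g$exons
    GRanges(g$contig,
            IRanges(vapply(ex, `[`, numeric(1), 1),
                    vapply(ex, `[`, numeric(1), 2)), strand = g$strand)
  }))
  names(exons) <- ids
  cds <- list()
  for (g in genes) {
    if (!is.null(g$cds)) {
      cds[[g$id]] <- GRanges(
        g$contig, IRanges(vapply(g$cds, `[`, numeric(1), 1),
                          vapply(g$cds, `[`, numeric(1), 2)),
        strand = g$strand)
    }
  }
  GeneModels(spans, exons, GRangesList(cds))
}

## narrowPeak-style GRanges from vectors (scores rounded the way a peak
## caller prints them)
buildPeaks <- function(contig, start, end, qValue,
                       summit = rep(NA_integer_, length(start)),
                       signalValue = rep(5, length(start)),
                       name = sprintf("pk%d", seq_along(start))) {
  gr <- GRanges(contig, IRanges(start, end))
  mcols(gr) <- S4Vectors::DataFrame(
    name = name, score = as.integer(round(10 * qValue)),
    signalValue = signalValue, pValue = qValue + 1, qValue = qValue,
    peak = as.integer(summit))
  gr
}

## a single reconciled signal centered at `center` (identical peak pair)
buildSignalAt <- function(contig, center, halfWidth = 150, qValue = 10,
                          signalValue = 5) {
  pk <- buildPeaks(contig, center - halfWidth, center + halfWidth,
                   qValue = qValue, summit = halfWidth,
                   signalValue = signalValue)
  reconcileReplicates(pk, pk)
}
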