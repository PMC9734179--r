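#' Filter peaks by q-value threshold
#'
#' Keeps the peaks whose \eqn{-\log_{10} q} exceeds \eqn{-\log_{10}}(qMax),
#' i.e. whose adjusted significance is better than \code{qMax}. Thresholds
#' are converted to the \eqn{-\log_{10}} scale once, here; input order is
#' preserved. \code{qMax = 1} keeps everything.
#'
#' @param peaks \code{GRanges} with a \code{qValue} metadata column
#'   (\eqn{-\log_{10}} scale).
#' @param qMax q-value threshold in (0, 1], e.g. 0.005 for target calling or
#'   0.001 for motif-discovery input.
#' @return the filtered \code{GRanges}.
#' @export
filterPeaksByQ <- function(peaks, qMax) {
  checkProb(qMax, "qMax")
  if (!"qValue" %in% colnames(mcols(peaks)))
    stopf("peaks lack a qValue metadata column")
  if (qMax >= 1) return(peaks)
  peaks[mcols(peaks)$qValue > -log10(qMax)]
}

## Exact maximum-cardinality, minimum-total-distance one-to-one matching of
## two sets of 1-D anchor positions under |a - b| <= maxD eligibility.
## Non-crossing DP over anchor-sorted lists is optimal for absolute-distance
## costs on a line (uncrossing exchange preserves eligibility and never
## increases total distance). Returns a 2-column index matrix (into the
## *sorted* inputs).
.matchAnchors1D <- function(a, b, maxD) {
  n <- length(a); m <- length(b)
  if (!n || !m) return(matrix(integer(), ncol = 2))
  BIG <- 1e18
  ## suffix DP: cnt[i,j], dst[i,j] = optimum for a[i..n], b[j..m]
  cnt <- matrix(0L, n + 1L, m + 1L)
  dst <- matrix(0, n + 1L, m + 1L)
  for (i in n:1) {
    for (j in m:1) {
      bc <- cnt[i + 1L, j]; bd <- dst[i + 1L, j]          # skip a[i]
      if (cnt[i, j + 1L] > bc ||
          (cnt[i, j + 1L] == bc && dst[i, j + 1L] < bd)) { # skip b[j]
        bc <- cnt[i, j + 1L]; bd <- dst[i, j + 1L]
      }
      d <- abs(a[i] - b[j])
      if (d <= maxD) {
        mc <- cnt[i + 1L, j + 1L] + 1L
        md <- dst[i + 1L, j + 1L] + d
        if (mc > bc || (mc == bc && md < bd)) { bc <- mc; bd <- md }
      }
      cnt[i, j] <- bc; dst[i, j] <- bd
    }
  }
  ## deterministic, orientation-symmetric backtrack: prefer matching; on a
  ## forced skip advance the side with the smaller current anchor
  pairs <- matrix(integer(), ncol = 2)
  i <- 1L; j <- 1L
  while (i <= n && j <= m) {
    d <- abs(a[i] - b[j])
    if (d <= maxD &&
        cnt[i, j] == cnt[i + 1L, j + 1L] + 1L &&
        dst[i, j] == dst[i + 1L, j + 1L] + d) {
      pairs <- rbind(pairs, c(i, j))
      i <- i + 1L; j <- j + 1L
    } else {
      skipA <- cnt[i, j] == cnt[i + 1L, j] && dst[i, j] == dst[i + 1L, j]
      skipB <- cnt[i, j] == cnt[i, j + 1L] && dst[i, j] == dst[i, j + 1L]
      if (skipA && (!skipB || a[i] <= b[j])) i <- i + 1L
      else j <- j + 1L
    }
  }
  pairs
}

#' Reconcile peak calls from two biological replicates
#'
#' Two peaks — one per replicate, on the same contig — are considered the
#' same reproducible binding signal when their anchors lie within
#' \code{maxDistance} bp of each other (within 1 kb by default; the bound is
#' inclusive). The anchor is the reported summit when present, otherwise the
#' interval midpoint. Among all eligible pairings the function returns the
#' one-to-one matching of maximal size that minimises the total anchor
#' distance, computed exactly per contig; peaks separated by more than
#' \code{maxDistance} from any opposite-replicate peak cannot interact, so
#' the problem decomposes into small independent blocks. Each reconciled
#' signal carries a representative peak — the member with the larger
#' \eqn{-\log_{10} q} — and a center, the midpoint of the two anchors.
#'
#' @param repA,repB \code{GRanges} of (q-filtered) peaks with narrowPeak
#'   metadata columns.
#' @param maxDistance reproducibility bound in bp (default 1000).
#' @param useSummit use the summit as anchor when available (default); if
#'   \code{FALSE}, always anchor at the interval midpoint.
#' @return a \code{\link{ReconciledPeaks}} object.
#' @examples
#' tf <- tempfile(); writeLines(c(
#'   "chr1\t100\t400\ta1\t0\t.\t5\t12\t10\t150",
#'   "chr1\t5000\t5400\ta2\t0\t.\t6\t14\t11\t200"), tf)
#' a <- readNarrowPeak(tf)
#' b <- GenomicRanges::shift(a, 120)
#' rp <- reconcileReplicates(a, b)
#' anchorDistances(rp)
#' @export
reconcileReplicates <- function(repA, repB, maxDistance = 1000,
                                useSummit = TRUE) {
  if (maxDistance < 0) stopf("maxDistance must be nonnegative")
  anchA <- peakAnchors(repA, useSummit)
  anchB <- peakAnchors(repB, useSummit)
  chrA <- as.character(seqnames(repA))
  chrB <- as.character(seqnames(repB))
  contigs <- sort(unique(c(chrA, chrB)))
  ia <- integer(); ib <- integer()
  for (ctg in contigs) {
    idxA <- which(chrA == ctg); idxB <- which(chrB == ctg)
    if (!length(idxA) || !length(idxB)) next
    oA <- idxA[order(anchA[idxA], idxA)]
    oB <- idxB[order(anchB[idxB], idxB)]
    ## split into blocks separated by > maxDistance in the merged anchor order
    pos <- c(anchA[oA], anchB[oB])
    side <- rep(c(1L, 2L), c(length(oA), length(oB)))
    o <- order(pos)
    brk <- c(0L, which(diff(pos[o]) > maxDistance), length(pos))
    for (k in seq_len(length(brk) - 1L)) {
      sel <- o[(brk[k] + 1L):brk[k + 1L]]
      selA <- sort(sel[side[sel] == 1L])
      selB <- sort(sel[side[sel] == 2L] - length(oA))
      if (!length(selA) || !length(selB)) next
      pr <- .matchAnchors1D(anchA[oA[selA]], anchB[oB[selB]], maxDistance)
      if (nrow(pr)) {
        ia <- c(ia, oA[selA][pr[, 1L]])
        ib <- c(ib, oB[selB][pr[, 2L]])
      }
    }
  }
  pkA <- repA[ia]; pkB <- repB[ib]
  dist <- abs(anchA[ia] - anchB[ib])
  center <- as.integer(floor((anchA[ia] + anchB[ib]) / 2))
  fromA <- mcols(pkA)$qValue >= mcols(pkB)$qValue
  rep <- pkA
  if (any(!fromA)) rep[!fromA] <- pkB[!fromA]
  mcols(rep)$center <- center
  mcols(rep)$anchor_distance <- as.integer(dist)
  mcols(rep)$source <- ifelse(fromA, "A", "B")
  ord <- order(as.character(seqnames(rep)), center,
               pmin(anchA[ia], anchB[ib]))
  new("ReconciledPeaks",
      representative = rep[ord], peakA = pkA[ord], peakB = pkB[ord],
      unmatchedA = repA[setdiff(seq_along(repA), ia)],
      unmatchedB = repB[setdiff(seq_along(repB), ib)],
      maxDistance = maxDistance)
}

#' Extract peak-center windows for motif-discovery input
#'
#' Returns the forward-strand, upper-cased sequence of the window of
#' \code{flank} bases either side of each reconciled signal center (300 bp
#' for the default 150-bp flank), clipped at contig boundaries. These
#' windows are the standard input to de novo motif discovery.
#'
#' @param genome a \code{DNAStringSet} (names = contigs).
#' @param signals a \code{\link{ReconciledPeaks}} object.
#' @param flank half-window size in bp (default 150).
#' @return \code{DNAStringSet} named \code{contig:start-end}, with metadata
#'   columns \code{contig}, \code{start}, \code{end}, \code{center},
#'   \code{clipped}.
#' @export
extractPeakWindow <- function(genome, signals, flank = 150) {
  if (flank < 1) stopf("flank must be positive")
  rep <- representative(signals)
  ctg <- as.character(seqnames(rep))
  unknown <- setdiff(unique(ctg), names(genome))
  if (length(unknown))
    stopf("contig not present in genome: %s", unknown[1L])
  centers <- signalCenters(signals)
  lens <- Biostrings::width(genome)[match(ctg, names(genome))]
  s <- pmax(1L, centers - as.integer(flank))
  e <- pmin(lens, centers + as.integer(flank) - 1L)
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(ctg), function(i) {
    toupper(as.character(Biostrings::subseq(genome[[ctg[i]]], s[i], e[i])))
  }, character(1)))
  names(seqs) <- sprintf("%s:%d-%d", ctg, s, e)
  mcols(seqs) <- DataFrame(contig = ctg, start = s, end = e,
                           center = centers,
                           clipped = (centers - flank < 1L) |
                             (centers + flank - 1L > lens))
  seqs
}
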