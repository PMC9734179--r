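#' Parse "contig:first-last" region strings
#'
#' Region strings use the 1-based inclusive convention, e.g.
#' \code{"NC_037652.1:7063408-7063595"} denotes a 188-bp interval.
#' Parsing and \code{\link{formatRegionString}} are exact inverses for all
#' valid inputs.
#'
#' @param x character vector of region strings.
#' @return \code{GRanges}, one range per input string (unstranded).
#' @examples
#' gr <- parseRegionString("NC_037652.1:7063408-7063595")
#' GenomicRanges::width(gr)  # 188
#' formatRegionString(gr)
#' @export
parseRegionString <- function(x) {
  if (!is.character(x) || !length(x))
    stopf("region string input must be a non-empty character vector")
  m <- regmatches(x, regexec("^(.+):([0-9]+)-([0-9]+)$", x))
  bad <- lengths(m) != 4L
  if (any(bad))
    stopf("malformed region string: '%s'", x[which(bad)[1L]])
  contig <- vapply(m, `[`, character(1), 2L)
  first <- as.numeric(vapply(m, `[`, character(1), 3L))
  last <- as.numeric(vapply(m, `[`, character(1), 4L))
  if (any(first < 1))
    stopf("region coordinates are 1-based; got start %s in '%s'",
          first[first < 1][1L], x[first < 1][1L])
  if (any(first > last))
    stopf("region start exceeds end in '%s'", x[first > last][1L])
  GRanges(contig, IRanges(first, last))
}

#' @rdname parseRegionString
#' @param gr a \code{GRanges} object.
#' @export
formatRegionString <- function(gr) {
  sprintf("%s:%d-%d", as.character(seqnames(gr)), start(gr), end(gr))
}

## Recycle two parallel GRanges to a common length for pairwise ops.
.pairRecycle <- function(a, b) {
  if (length(a) != length(b)) {
    if (length(a) == 1L) a <- rep(a, length(b))
    else if (length(b) == 1L) b <- rep(b, length(a))
    else stopf("pairwise interval operations need equal lengths (or one scalar)")
  }
  list(a = a, b = b)
}

#' Pairwise interval arithmetic
#'
#' Element-wise operations on parallel \code{GRanges}. \code{intervalOverlap}
#' returns the number of shared bases (0 across contigs);
#' \code{intervalDistance} the gap in bases between two intervals on the same
#' contig (0 when they overlap or abut; an error across contigs);
#' \code{intervalIntersection} their intersection (zero-length ranges where
#' disjoint). Abutting intervals — e.g. bases 101..200 and 201..300 — have
#' overlap 0 and distance 0.
#'
#' @param a,b \code{GRanges} of equal length (or either of length 1).
#' @return \code{intervalOverlap}, \code{intervalDistance}: integer vectors;
#'   \code{intervalIntersection}: \code{GRanges} (zero-width where empty).
#' @examples
#' a <- GenomicRanges::GRanges("c", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("c", IRanges::IRanges(151, 250))
#' intervalOverlap(a, b)    # 50
#' intervalDistance(a, b)   # 0
#' @export
intervalOverlap <- function(a, b) {
  p <- .pairRecycle(a, b)
  same <- as.character(seqnames(p$a)) == as.character(seqnames(p$b))
  ov <- pmin(end(p$a), end(p$b)) - pmax(start(p$a), start(p$b)) + 1L
  as.integer(ifelse(same, pmax(0L, ov), 0L))
}

#' @rdname intervalOverlap
#' @export
intervalDistance <- function(a, b) {
  p <- .pairRecycle(a, b)
  same <- as.character(seqnames(p$a)) == as.character(seqnames(p$b))
  if (!all(same))
    stopf("distance is undefined across contigs (%s vs %s)",
          as.character(seqnames(p$a))[!same][1L],
          as.character(seqnames(p$b))[!same][1L])
  gap <- pmax(start(p$a) - end(p$b) - 1L, start(p$b) - end(p$a) - 1L, 0L)
  as.integer(gap)
}

#' @rdname intervalOverlap
#' @export
intervalIntersection <- function(a, b) {
  p <- .pairRecycle(a, b)
  same <- as.character(seqnames(p$a)) == as.character(seqnames(p$b))
  s <- pmax(start(p$a), start(p$b))
  e <- pmin(end(p$a), end(p$b))
  empty <- !same | s > e
  ## represent empty results as zero-width ranges at the a-side start
  s[empty] <- start(p$a)[empty]
  e[empty] <- start(p$a)[empty] - 1L
  out <- GRanges(seqnames(p$a), IRanges(s, e))
  mcols(out)$empty <- empty
  out
}
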