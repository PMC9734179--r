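## narrowPeak (ENCODE BED6+4) reader/writer.
##
## Peaks are represented as GRanges with metadata columns
##   name (character), score (integer), signalValue (fold enrichment),
##   pValue, qValue (-log10 scale, as printed), peak (summit offset from the
##   0-based interval start; NA when the caller reported -1).

.npCols <- c("name", "score", "signalValue", "pValue", "qValue", "peak")

#' Read and write ENCODE narrowPeak files
#'
#' \code{readNarrowPeak} parses a BED6+4 narrowPeak file into a
#' \code{GRanges}. BED's 0-based half-open coordinates become 1-based closed
#' ranges; the \code{pValue}/\code{qValue} columns hold \eqn{-\log_{10}}
#' values exactly as printed; a summit column of \code{-1} becomes
#' \code{NA}. \code{writeNarrowPeak} is the exact inverse.
#'
#' @param path file path.
#' @return \code{readNarrowPeak}: \code{GRanges} with metadata columns
#'   \code{name}, \code{score}, \code{signalValue}, \code{pValue},
#'   \code{qValue}, \code{peak}.
#' @examples
#' tf <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t100\t300\tp1\t50\t.\t5.2\t10.1\t7.3\t80", tf)
#' pk <- readNarrowPeak(tf)
#' summitPositions(pk)  # 181: 1-based absolute summit
#' @export
readNarrowPeak <- function(path) {
  if (!file.exists(path)) stopf("narrowPeak file not found: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (!length(nf)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(name = character(), score = integer(),
                           signalValue = numeric(), pValue = numeric(),
                           qValue = numeric(), peak = integer())
    return(gr)
  }
  bad <- which(nf != 10L)
  if (length(bad))
    stopf("narrowPeak format error at line %d of %s: expected 10 columns, found %d",
          bad[1L], path, nf[bad[1L]])
  d <- utils::read.delim(path, header = FALSE, quote = "",
                         comment.char = "", stringsAsFactors = FALSE,
                         colClasses = c("character", "numeric", "numeric",
                                        "character", "integer", "character",
                                        "numeric", "numeric", "numeric",
                                        "integer"))
  if (any(d$V2 < 0))
    stopf("negative start coordinate at line %d of %s", which(d$V2 < 0)[1L], path)
  if (any(d$V3 <= d$V2))
    stopf("empty or inverted interval at line %d of %s",
          which(d$V3 <= d$V2)[1L], path)
  sc <- c(d$V7, d$V8, d$V9)
  if (any(!is.finite(sc)) || any(sc < 0))
    stopf("non-finite or negative score values in %s", path)
  summit <- d$V10
  if (any(summit < -1L))
    stopf("invalid summit offset at line %d of %s",
          which(summit < -1L)[1L], path)
  width <- d$V3 - d$V2
  if (any(summit >= width & summit >= 0L))
    stopf("summit offset outside the peak interval at line %d of %s",
          which(summit >= width & summit >= 0L)[1L], path)
  summit[summit == -1L] <- NA_integer_
  gr <- GRanges(d$V1, IRanges(d$V2 + 1L, d$V3), strand = fixStrand(d$V6))
  mcols(gr) <- DataFrame(name = d$V4, score = as.integer(d$V5),
                         signalValue = d$V7, pValue = d$V8, qValue = d$V9,
                         peak = summit)
  gr
}

#' @rdname readNarrowPeak
#' @param peaks \code{GRanges} with the narrowPeak metadata columns.
#' @export
writeNarrowPeak <- function(peaks, path) {
  mc <- mcols(peaks)
  miss <- setdiff(.npCols, colnames(mc))
  if (length(miss))
    stopf("peaks lack narrowPeak metadata column(s): %s",
          paste(miss, collapse = ", "))
  summit <- mc$peak
  summit[is.na(summit)] <- -1L
  strandChr <- as.character(strand(peaks))
  strandChr[strandChr == "*"] <- "."
  d <- data.frame(as.character(seqnames(peaks)), start(peaks) - 1L,
                  end(peaks), mc$name, mc$score, strandChr,
                  mc$signalValue, mc$pValue, mc$qValue, summit)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Absolute summit-or-midpoint anchor of peaks
#'
#' The anchor is the summit position when the caller reported one, otherwise
#' the interval midpoint; it is the point used by replicate reconciliation.
#' \code{summitPositions} returns the absolute 1-based summit (NA when
#' absent).
#'
#' @param peaks \code{GRanges} with narrowPeak metadata columns.
#' @param useSummit if \code{FALSE}, always use the interval midpoint.
#' @return integer vector of 1-based genomic positions.
#' @export
peakAnchors <- function(peaks, useSummit = TRUE) {
  mid <- as.integer(floor((start(peaks) + end(peaks)) / 2))
  if (!useSummit || !"peak" %in% colnames(mcols(peaks))) return(mid)
  s <- summitPositions(peaks)
  ifelse(is.na(s), mid, s)
}

#' @rdname peakAnchors
#' @export
summitPositions <- function(peaks) {
  off <- mcols(peaks)$peak
  as.integer(start(peaks) + off)  # 1-based start + 0-based offset
}
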