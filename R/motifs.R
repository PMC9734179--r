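#' Motif specification with IUPAC codes and one optional base
#'
#' A motif pattern is a string over the DNA alphabet plus IUPAC ambiguity
#' codes, with at most one parenthesised optional base: \code{"AT(C)TTTGTA"}
#' expands to the two plain patterns \code{ATCTTTGTA} and \code{ATTTTGTA}.
#'
#' @param name motif name (e.g. \code{"GAGA"}).
#' @param pattern pattern string.
#' @return a \code{MotifSpec} object.
#' @examples
#' expandMotif(motifSpec("m3", "AT(C)TTTGTA"))
#' @export
motifSpec <- function(name, pattern) {
  new("MotifSpec", name = name, pattern = pattern)
}

#' @rdname motifSpec
#' @export
setClass("MotifSpec",
         representation(name = "character", pattern = "character"))

setValidity("MotifSpec", function(object) {
  p <- object@pattern
  if (length(p) != 1L || is.na(p)) return("pattern must be a single string")
  nopt <- lengths(regmatches(p, gregexpr("\\([A-Za-z]\\)", p)))
  if (grepl("[()]", gsub("\\([A-Za-z]\\)", "", p)) || nopt > 1L)
    return("at most one parenthesised optional base is allowed")
  core <- gsub("[()]", "", p)
  iupac <- strsplit("ACGTRYSWKMBDHVN", "")[[1L]]
  bad <- setdiff(strsplit(toupper(core), "")[[1L]], iupac)
  if (length(bad))
    return(sprintf("invalid IUPAC code(s) in pattern: %s",
                   paste(unique(bad), collapse = ", ")))
  if (nchar(gsub("\\([A-Za-z]\\)", "", p)) < 2L)
    return("pattern must have length >= 2 outside the optional base")
  TRUE
})

setMethod("show", "MotifSpec", function(object) {
  cat(sprintf("MotifSpec %s: %s (expands to %s)\n", object@name,
              object@pattern, paste(expandMotif(object), collapse = ", ")))
})

#' @rdname motifSpec
#' @param spec a \code{MotifSpec} object.
#' @export
expandMotif <- function(spec) {
  p <- toupper(spec@pattern)
  if (grepl("\\([A-Z]\\)", p)) {
    withBase <- gsub("[()]", "", p)
    without <- gsub("\\([A-Z]\\)", "", p)
    unique(c(withBase, without))
  } else p
}

#' Count motif occurrences, allowing overlap
#'
#' Counts every start position at which the plain motif occurs in the
#' sequence, so overlapping occurrences all count: \code{GAGA} contains one
#' GAGA and one GAG, and \code{GAGAG} contains one GAGA and two GAGs.
#' Matching is literal; \code{N} (or any non-ACGT letter) never matches.
#'
#' @param sequence a character string, \code{DNAString}, or
#'   \code{DNAStringSet} element.
#' @param motif plain motif string over A/C/G/T.
#' @return integer count.
#' @examples
#' countOverlapping("GAGAG", "GAG")   # 2
#' countOverlapping("GAGAGA", "GAGA") # 2
#' @export
countOverlapping <- function(sequence, motif) {
  motif <- toupper(as.character(motif))
  if (!nzchar(motif)) stopf("motif must be a non-empty string")
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L) stopf("sequence must be a single string")
  n <- nchar(sequence); k <- nchar(motif)
  if (n < k) return(0L)
  starts <- seq_len(n - k + 1L)
  sum(substring(sequence, starts, starts + k - 1L) == motif)
}

#' Scan a sequence for a motif specification
#'
#' Matches the union of the plain expansions of \code{spec} (optional base
#' in or out; IUPAC codes interpreted as ambiguity in the pattern only, so
#' \code{N} in the sequence never matches), allowing overlapping matches.
#' With \code{countBothStrands}, reverse-complement expansions are also
#' scanned against the forward sequence and reported with strand
#' \code{"-"}; hits are de-duplicated by (position, strand).
#'
#' @param sequence character, \code{DNAString}, or single-sequence input.
#' @param spec a \code{\link{motifSpec}} object.
#' @param countBothStrands also scan the reverse strand (default
#'   \code{FALSE}; counting is gene-sense only by default).
#' @return \code{list(positions = data.frame(start, width, strand),
#'   count = integer)}.
#' @export
scanMotif <- function(sequence, spec, countBothStrands = FALSE) {
  stopifnot(is(spec, "MotifSpec"))
  subject <- Biostrings::DNAString(toupper(as.character(sequence)))
  pats <- expandMotif(spec)
  hitOne <- function(pat, strandChr) {
    if (length(subject) < nchar(pat))
      return(data.frame(start = integer(), width = integer(),
                        strand = character()))
    m <- Biostrings::matchPattern(pat, subject, fixed = "subject")
    data.frame(start = BiocGenerics::start(m),
               width = BiocGenerics::width(m),
               strand = rep(strandChr, length(m)),
               stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, lapply(pats, hitOne, strandChr = "+"))
  if (countBothStrands) {
    rcs <- vapply(pats, function(p) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(p)))
    }, character(1))
    hits <- rbind(hits, do.call(rbind, lapply(rcs, hitOne, strandChr = "-")))
  }
  hits <- hits[!duplicated(hits[c("start", "strand")]), , drop = FALSE]
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  list(positions = hits, count = nrow(hits))
}

#' Extract TSS-upstream windows, oriented with the gene
#'
#' Returns the \code{length} bases immediately 5' of each gene's
#' transcription start site, in gene orientation (reverse-complemented for
#' minus-strand genes), clipped at contig boundaries. These are the windows
#' in which GA-rich motif accumulation is compared across species.
#'
#' @param genes a \code{\link{GeneModels}} object.
#' @param genome a \code{DNAStringSet} (names = contigs).
#' @param length window length in bp (2000 or 10000 in the standard
#'   analysis; any positive value is accepted).
#' @param geneId optional subset of gene ids (default: all).
#' @return \code{DNAStringSet} named by gene id with metadata columns
#'   \code{subject}, \code{window_length}, \code{contig}, \code{start},
#'   \code{end}, \code{strand}, \code{clipped}, \code{effective_length}.
#' @export
extractUpstream <- function(genes, genome, length = 2000, geneId = NULL) {
  if (length < 1) stopf("window length must be positive")
  gm <- if (is.null(geneId)) genes else genes[geneId]
  g <- geneRanges(gm)
  ids <- geneIds(gm)
  ctg <- as.character(seqnames(g))
  unknown <- setdiff(unique(ctg), names(genome))
  if (length(unknown))
    stopf("contig not present in genome: %s", unknown[1L])
  std <- as.character(strand(g))
  if (any(std == "*")) {
    warnf("gene(s) without strand treated as '+': %s",
          paste(ids[std == "*"], collapse = ", "))
    std[std == "*"] <- "+"
  }
  tssPos <- tss(gm)
  ctgLen <- Biostrings::width(genome)[match(ctg, names(genome))]
  s <- ifelse(std == "+", pmax(1L, tssPos - as.integer(length)), tssPos + 1L)
  e <- ifelse(std == "+", tssPos - 1L,
              pmin(ctgLen, tssPos + as.integer(length)))
  clipped <- ifelse(std == "+", tssPos - length < 1L,
                    tssPos + length > ctgLen)
  empty <- s > e
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(g), function(i) {
    if (empty[i]) return("")
    x <- Biostrings::subseq(genome[[ctg[i]]], s[i], e[i])
    if (std[i] == "-") x <- Biostrings::reverseComplement(x)
    toupper(as.character(x))
  }, character(1)))
  names(seqs) <- ids
  mcols(seqs) <- DataFrame(subject = ids, window_length = as.integer(length),
                           contig = ctg,
                           start = as.integer(ifelse(empty, NA, s)),
                           end = as.integer(ifelse(empty, NA, e)),
                           strand = std, clipped = clipped,
                           effective_length = as.integer(ifelse(empty, 0L,
                                                                e - s + 1L)))
  seqs
}

#' Per-subject motif count table
#'
#' Builds the full cross-product of subjects, window lengths and motifs from
#' a collection of upstream windows, counting motif occurrences with
#' overlaps allowed. A subject/window combination with no extracted record
#' is reported with \code{present = FALSE} and an \code{NA} count — absent,
#' not zero.
#'
#' @param upstream \code{DNAStringSet} with metadata columns \code{subject}
#'   and \code{window_length} (e.g. concatenated outputs of
#'   \code{\link{extractUpstream}} with \code{subject} renamed to species).
#' @param motifs named character vector of plain motifs
#'   (default \code{c(GAGA = "GAGA", GAG = "GAG")}).
#' @param windows window lengths to tabulate (default \code{c(2000, 10000)}).
#' @param subjects subject order (default: order of first appearance).
#' @return \code{data.frame} with columns \code{subject},
#'   \code{window_length}, \code{motif}, \code{count}, \code{present}.
#' @export
speciesMotifTable <- function(upstream,
                              motifs = c(GAGA = "GAGA", GAG = "GAG"),
                              windows = c(2000, 10000),
                              subjects = NULL) {
  mc <- mcols(upstream)
  if (is.null(mc) || !all(c("subject", "window_length") %in% colnames(mc)))
    stopf("upstream records need 'subject' and 'window_length' metadata")
  if (is.null(names(motifs)) || any(!nzchar(names(motifs))))
    stopf("motifs must be a named character vector")
  if (is.null(subjects)) subjects <- unique(as.character(mc$subject))
  rows <- list()
  for (sb in subjects) {
    for (w in windows) {
      hit <- which(as.character(mc$subject) == sb & mc$window_length == w)
      for (k in seq_along(motifs)) {
        cnt <- if (length(hit)) {
          countOverlapping(as.character(upstream[[hit[1L]]]), motifs[[k]])
        } else NA_integer_
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sb, window_length = as.integer(w),
          motif = names(motifs)[k], count = as.integer(cnt),
          present = length(hit) > 0L, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Grouped bar chart of per-subject motif counts
#'
#' Draws one group of bars per subject with one bar per motif, for a single
#' window length — the conventional display of GA-rich motif accumulation
#' across species.
#'
#' @param tbl output of \code{\link{speciesMotifTable}}.
#' @param window which window length to plot (default: the smallest present).
#' @param file optional PNG path; when given, the plot is written there.
#' @return invisibly, the count matrix plotted.
#' @export
plotMotifCounts <- function(tbl, window = NULL, file = NULL) {
  if (is.null(window)) window <- min(tbl$window_length)
  d <- tbl[tbl$window_length == window & tbl$present, , drop = FALSE]
  m <- tapply(d$count, list(d$motif, d$subject), identity)
  m <- m[, unique(d$subject), drop = FALSE]
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 700, res = 130)
    on.exit(grDevices::dev.off())
  }
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    col = c("goldenrod1", "grey60")[seq_len(nrow(m))],
                    ylab = sprintf("motif count in %d bp upstream", window),
                    las = 2)
  invisible(m)
}
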