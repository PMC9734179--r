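#' Assign reconciled binding signals to candidate target genes
#'
#' A (signal, gene) pair is emitted when the signal lies within
#' \code{window} bp of the gene — by default when the representative peak
#' interval overlaps the gene span extended by \code{window} on both sides
#' (equivalently, interval-to-span gap distance \eqn{\le} \code{window},
#' inclusive at the boundary). Every qualifying gene is emitted, so a signal
#' with several genes in range yields several rows, and a signal with none
#' yields a single row with \code{NA} gene fields. Positional labels come
#' from \code{\link{classifyPosition}} applied at the signal center.
#'
#' @param signals a \code{\link{ReconciledPeaks}} object.
#' @param genes a \code{\link{GeneModels}} object.
#' @param window assignment window in bp (default 10000, i.e. within 10 kb
#'   upstream or downstream).
#' @param measure \code{"edge"} (default): qualify on representative-interval
#'   to gene-span distance; \code{"center"}: measure from the signal center
#'   instead.
#' @return \code{data.frame} with one row per (signal, gene) pair: columns
#'   \code{signal}, \code{contig}, \code{center}, \code{fold_enrichment},
#'   \code{neg_log10_q}, \code{gene_id}, \code{description},
#'   \code{position}, \code{distance} (signed bp; 0 when the signal overlaps
#'   the gene, negative on the gene's upstream side).
#' @export
assignTargets <- function(signals, genes, window = 10000,
                          measure = c("edge", "center")) {
  measure <- match.arg(measure)
  if (window < 0) stopf("window must be nonnegative")
  rep <- representative(signals)
  centers <- signalCenters(signals)
  g <- geneRanges(genes)
  query <- if (measure == "edge") granges(rep)
           else GRanges(seqnames(rep), IRanges(centers, centers))
  ## suppressWarnings: signals and genes may legitimately live on disjoint
  ## contig sets (GenomicRanges warns about merged seqlevels)
  hits <- suppressWarnings(
    findOverlaps(query, g, maxgap = window, ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ids <- geneIds(genes)
  rows <- lapply(seq_along(rep), function(i) {
    js <- sh[qh == i]
    base <- data.frame(signal = i,
                       contig = as.character(seqnames(rep))[i],
                       center = centers[i],
                       fold_enrichment = mcols(rep)$signalValue[i],
                       neg_log10_q = mcols(rep)$qValue[i],
                       stringsAsFactors = FALSE)
    if (!length(js)) {
      return(cbind(base, data.frame(gene_id = NA_character_,
                                    description = NA_character_,
                                    position = NA_character_,
                                    distance = NA_integer_)))
    }
    js <- js[order(start(g)[js], ids[js])]
    do.call(rbind, lapply(js, function(j) {
      cbind(base, data.frame(
        gene_id = ids[j],
        description = as.character(mcols(g)$description[j]),
        position = classifyPosition(genes, ids[j], centers[i]),
        distance = .signedDistance(rep[i], centers[i], g[j]),
        stringsAsFactors = FALSE))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## signed interval-to-span distance: 0 when overlapping, negative on the
## gene's upstream (TSS) side
.signedDistance <- function(signal, center, gene) {
  d <- intervalOverlap(granges(signal), granges(gene))
  if (d > 0) return(0L)
  gap <- intervalDistance(granges(signal), granges(gene))
  std <- as.character(strand(gene))
  if (std == "*") std <- "+"
  leftOfGene <- center < start(gene)
  upstream <- (std == "+" & leftOfGene) | (std == "-" & !leftOfGene)
  as.integer(if (upstream) -gap else gap)
}

#' Classify a signal position relative to a gene
#'
#' Applied at the signal center: inside the gene span the label is
#' \code{5'UTR} or \code{3'UTR} when the center falls in an annotated UTR
#' (only genes with CDS records get UTR labels), else \code{Exon} when in an
#' exon, else \code{Intron}; outside the span it is \code{Upstream} on the
#' TSS side of the gene (strand-aware) and \code{Downstream} on the other
#' side. Unstranded genes are labelled as if on the plus strand, with a
#' warning.
#'
#' @param genes a \code{\link{GeneModels}} object.
#' @param geneId a single gene id.
#' @param center 1-based genomic position of the signal center (same contig
#'   as the gene).
#' @return one of \code{"5'UTR"}, \code{"3'UTR"}, \code{"Exon"},
#'   \code{"Intron"}, \code{"Upstream"}, \code{"Downstream"}.
#' @export
classifyPosition <- function(genes, geneId, center) {
  i <- match(geneId, geneIds(genes))
  if (is.na(i)) stopf("unknown gene id: %s", geneId)
  g <- geneRanges(genes)[i]
  std <- as.character(strand(g))
  if (std == "*") {
    warnf("gene %s has no strand; treating as '+' for position labels", geneId)
    std <- "+"
  }
  if (center >= start(g) && center <= end(g)) {
    utr <- utrRegions(genes, geneId)
    inRange <- function(gr) length(gr) &&
      any(center >= start(gr) & center <= end(gr))
    if (!is.null(utr)) {
      if (inRange(utr$utr5)) return("5'UTR")
      if (inRange(utr$utr3)) return("3'UTR")
    }
    e <- exonStructure(genes)[[i]]
    if (inRange(e)) return("Exon")
    return("Intron")
  }
  leftOfGene <- center < start(g)
  upstream <- (std == "+" && leftOfGene) || (std == "-" && !leftOfGene)
  if (upstream) "Upstream" else "Downstream"
}

#' Ranked report of the strongest binding signals
#'
#' Orders signals by \eqn{-\log_{10} q} descending (ties: fold enrichment
#' descending, then contig and coordinate), keeps the top \code{topN}, and
#' expands signals with several genes in range to side-numbered rows (e.g.
#' \code{2-1}, \code{2-2}), mirroring a top-signals table: signal statistics
#' are printed on the first row of each signal only.
#'
#' @param assignments \code{data.frame} from \code{\link{assignTargets}}.
#' @param topN number of signals to report (default 20).
#' @return \code{data.frame} with columns \code{gene_no}, \code{gene_id},
#'   \code{description}, \code{fold_enrichment}, \code{neg_log10_q},
#'   \code{position}.
#' @export
rankSignalReport <- function(assignments, topN = 20) {
  if (!is.numeric(topN) || length(topN) != 1L || topN < 1)
    stopf("topN must be a positive integer")
  sig <- unique(assignments[c("signal", "contig", "center",
                              "fold_enrichment", "neg_log10_q")])
  ord <- order(-sig$neg_log10_q, -sig$fold_enrichment, sig$contig, sig$center)
  sig <- sig[ord, , drop = FALSE]
  sig <- utils::head(sig, topN)
  out <- lapply(seq_len(nrow(sig)), function(r) {
    rows <- assignments[assignments$signal == sig$signal[r], , drop = FALSE]
    multi <- nrow(rows) > 1L
    data.frame(
      gene_no = if (multi) sprintf("%d-%d", r, seq_len(nrow(rows)))
                else as.character(r),
      gene_id = rows$gene_id,
      description = rows$description,
      fold_enrichment = c(rows$fold_enrichment[1L],
                          rep(NA_real_, nrow(rows) - 1L)),
      neg_log10_q = c(rows$neg_log10_q[1L], rep(NA_real_, nrow(rows) - 1L)),
      position = rows$position,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare two condition-specific target gene sets
#'
#' Exact set algebra between two gene-id vectors (duplicates are dropped):
#' shared ids, ids specific to either set, and specific/common fractions.
#' \code{fractionsPercent} reports the fractions as whole percentages,
#' rounded half-up (so 138/263 displays as 52\%).
#'
#' @param a,b character vectors of gene ids.
#' @return a \code{\link{TargetSetComparison}} object.
#' @examples
#' cmp <- compareTargetSets(letters[1:5], letters[4:10])
#' fractionsPercent(cmp)
#' @export
compareTargetSets <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  common <- intersect(a, b)
  aSpec <- setdiff(a, b); bSpec <- setdiff(b, a)
  frac <- function(num, den) if (den == 0) 0 else num / den
  fractions <- c(a_specific = frac(length(aSpec), length(a)),
                 b_specific = frac(length(bSpec), length(b)),
                 common_in_a = frac(length(common), length(a)),
                 common_in_b = frac(length(common), length(b)))
  new("TargetSetComparison", setA = a, setB = b, common = common,
      aSpecific = aSpec, bSpecific = bSpec, fractions = fractions)
}

#' @rdname compareTargetSets
#' @param x a \code{TargetSetComparison} object.
#' @export
fractionsPercent <- function(x) {
  stopifnot(is(x, "TargetSetComparison"))
  roundHalfUp(100 * x@fractions)
}

#' @rdname compareTargetSets
#' @export
commonIds <- function(x) { stopifnot(is(x, "TargetSetComparison")); x@common }

#' @rdname compareTargetSets
#' @param which \code{"A"} or \code{"B"}.
#' @export
specificIds <- function(x, which = c("A", "B")) {
  stopifnot(is(x, "TargetSetComparison"))
  if (match.arg(which) == "A") x@aSpecific else x@bSpecific
}
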