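#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width
#'   strand findOverlaps
#' @importFrom IRanges IRanges
NULL

#' Gene models with exon structure
#'
#' Container for a gene catalog: one record per gene with its genomic span,
#' strand, description and biotype, plus per-gene exon and (optionally) CDS
#' intervals. Multi-isoform genes are collapsed to their union span and union
#' exon set, matching how binding signals are annotated per gene rather than
#' per transcript.
#'
#' @slot genes \code{GRanges} with one range per gene and metadata columns
#'   \code{gene_id}, \code{description}, \code{biotype}.
#' @slot exons \code{GRangesList} named by \code{gene_id}; sorted,
#'   non-overlapping exon intervals within the gene span.
#' @slot cds \code{GRangesList} named by \code{gene_id} for the subset of
#'   genes with annotated coding sequence (may be empty).
#'
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 3000), "+")
#' S4Vectors::mcols(g) <- S4Vectors::DataFrame(
#'   gene_id = "LOC1", description = "example", biotype = "protein_coding")
#' ex <- GenomicRanges::GRangesList(
#'   LOC1 = GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(1001, 2501), c(1400, 3000)), "+"))
#' gm <- GeneModels(g, ex)
#' tss(gm)
#' @export
setClass("GeneModels",
  representation(genes = "GRanges", exons = "GRangesList",
                 cds = "GRangesList"))

setValidity("GeneModels", function(object) {
  g <- object@genes
  ids <- mcols(g)$gene_id
  msgs <- character()
  need <- c("gene_id", "description", "biotype")
  miss <- setdiff(need, colnames(mcols(g)))
  if (length(miss))
    return(sprintf("missing gene metadata column(s): %s",
                   paste(miss, collapse = ", ")))
  if (anyDuplicated(ids))
    msgs <- c(msgs, "duplicated gene_id values")
  if (!identical(names(object@exons), as.character(ids)))
    msgs <- c(msgs, "exon list names must equal gene_id, in order")
  if (length(object@cds) &&
      !all(names(object@cds) %in% ids))
    msgs <- c(msgs, "cds list names must be a subset of gene_id")
  ## every exon inside its parent span, same contig and strand
  if (length(g)) {
    exu <- BiocGenerics::unlist(object@exons, use.names = TRUE)
    idx <- match(names(exu), ids)
    bad <- as.character(seqnames(exu)) != as.character(seqnames(g))[idx] |
      start(exu) < start(g)[idx] | end(exu) > end(g)[idx]
    if (any(bad))
      msgs <- c(msgs, sprintf("exon outside parent gene span for gene(s): %s",
                              paste(unique(names(exu)[bad]), collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Reconciled replicate peak pairs
#'
#' Result of matching q-filtered peak calls from two biological replicates
#' under the within-\code{maxDistance} reproducibility rule. Each reconciled
#' signal keeps both member peaks, the anchor distance between them, the
#' representative member (the one with the larger \eqn{-\log_{10} q}), and
#' the signal center (midpoint of the two anchors), plus the peaks of either
#' replicate that found no partner.
#'
#' @slot representative \code{GRanges} of the representative member per pair,
#'   carrying the narrowPeak metadata columns plus \code{center},
#'   \code{anchor_distance} and \code{source} ("A" or "B").
#' @slot peakA,peakB \code{GRanges}, the member peaks, parallel to
#'   \code{representative}.
#' @slot unmatchedA,unmatchedB \code{GRanges} of unpaired peaks.
#' @slot maxDistance numeric, the reproducibility distance bound in bp.
#' @export
setClass("ReconciledPeaks",
  representation(representative = "GRanges", peakA = "GRanges",
                 peakB = "GRanges", unmatchedA = "GRanges",
                 unmatchedB = "GRanges", maxDistance = "numeric"))

setValidity("ReconciledPeaks", function(object) {
  n <- length(object@representative)
  if (length(object@peakA) != n || length(object@peakB) != n)
    return("member peak sets must be parallel to representatives")
  if (n) {
    mc <- mcols(object@representative)
    if (!all(c("center", "anchor_distance", "source") %in% colnames(mc)))
      return("representative must carry center/anchor_distance/source")
    if (any(as.character(seqnames(object@peakA)) !=
            as.character(seqnames(object@peakB))))
      return("paired peaks must share a contig")
    if (any(mc$anchor_distance > object@maxDistance))
      return("anchor_distance exceeds maxDistance")
    lo <- pmin(start(object@peakA), start(object@peakB))
    hi <- pmax(end(object@peakA), end(object@peakB))
    if (any(mc$center < lo | mc$center > hi))
      return("center outside the union of the member intervals")
  }
  TRUE
})

#' Comparison of two condition-specific target gene sets
#'
#' Exact set algebra between two gene-id sets (e.g. pupal vs adult binding
#' targets): shared members, members specific to either set, and the
#' corresponding fractions.
#'
#' @slot setA,setB character vectors of unique gene ids.
#' @slot common,aSpecific,bSpecific character vectors from the set algebra.
#' @slot fractions named numeric in [0, 1]: \code{a_specific}, \code{b_specific},
#'   \code{common_in_a}, \code{common_in_b}.
#' @export
setClass("TargetSetComparison",
  representation(setA = "character", setB = "character",
                 common = "character", aSpecific = "character",
                 bSpecific = "character", fractions = "numeric"))

setValidity("TargetSetComparison", function(object) {
  msgs <- character()
  if (length(object@aSpecific) + length(object@common) != length(object@setA))
    msgs <- c(msgs, "|a_specific| + |common| must equal |set_a|")
  if (length(object@bSpecific) + length(object@common) != length(object@setB))
    msgs <- c(msgs, "|b_specific| + |common| must equal |set_b|")
  f <- object@fractions
  if (length(f) && (any(is.na(f)) || any(f < 0) || any(f > 1)))
    msgs <- c(msgs, "fractions must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Pipeline configuration
#'
#' Holds the analysis constants: the q-value thresholds for target calling
#' (0.005) and motif-discovery input (0.001), the replicate reconciliation
#' distance (1 kb), the target-assignment window (10 kb), the peak-center
#' flank for motif input (150 bp), the TSS-upstream window lengths (2 kb and
#' 10 kb), the motif set (GAGA/GAG), the large-type Kenyon cell cluster ids
#' ({1,2,6,7}), and the marker-test parameters. Round-trips through YAML via
#' \code{\link{readPipelineConfig}} / \code{\link{writePipelineConfig}}.
#' @export
setClass("PipelineConfig",
  representation(qTarget = "numeric", qMotif = "numeric",
                 maxDistance = "numeric", targetWindow = "numeric",
                 flank = "numeric", upstreamLengths = "numeric",
                 motifs = "character", lkcClusters = "character",
                 markerMinFrac = "numeric", markerMinEffect = "numeric",
                 markerAlpha = "numeric", adjustMethod = "character",
                 seed = "numeric"))

setValidity("PipelineConfig", function(object) {
  msgs <- character()
  for (s in c("qTarget", "qMotif", "markerAlpha")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v <= 0 || v > 1)
      msgs <- c(msgs, sprintf("%s must be a single value in (0, 1]", s))
  }
  for (s in c("maxDistance", "targetWindow", "flank")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0)
      msgs <- c(msgs, sprintf("%s must be a single nonnegative value", s))
  }
  if (!length(object@upstreamLengths) || any(object@upstreamLengths <= 0))
    msgs <- c(msgs, "upstreamLengths must be positive")
  if (!length(object@motifs) || is.null(names(object@motifs)) ||
      any(!nzchar(names(object@motifs))))
    msgs <- c(msgs, "motifs must be a named character vector")
  if (length(object@adjustMethod) != 1L ||
      !object@adjustMethod %in% c("bonferroni", "BH"))
    msgs <- c(msgs, "adjustMethod must be 'bonferroni' or 'BH'")
  if (length(object@markerMinFrac) != 1L || object@markerMinFrac < 0 ||
      object@markerMinFrac > 1)
    msgs <- c(msgs, "markerMinFrac must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
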