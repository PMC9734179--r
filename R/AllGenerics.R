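#' @include AllClasses.R
NULL

#' @describeIn GeneModels number of genes
#' @param x,object a \code{GeneModels} (or other) object.
#' @export
setMethod("length", "GeneModels", function(x) length(x@genes))

#' Accessors for package classes
#'
#' \code{geneIds} returns the gene identifiers; \code{geneRanges} the gene
#' span \code{GRanges}; \code{exonStructure} / \code{cdsStructure} the
#' per-gene \code{GRangesList}; \code{tss} the 1-based transcription start
#' position per gene (span start on \code{+}, span end on \code{-};
#' unstranded genes fall back to the span start).
#'
#' @param x a \code{GeneModels} or \code{ReconciledPeaks} object.
#' @return See each generic's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setMethod("geneIds", "GeneModels", function(x) {
  as.character(mcols(x@genes)$gene_id)
})

#' @rdname accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @rdname accessors
#' @export
setMethod("geneRanges", "GeneModels", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("exonStructure", function(x) standardGeneric("exonStructure"))
#' @rdname accessors
#' @export
setMethod("exonStructure", "GeneModels", function(x) x@exons)

#' @rdname accessors
#' @export
setGeneric("cdsStructure", function(x) standardGeneric("cdsStructure"))
#' @rdname accessors
#' @export
setMethod("cdsStructure", "GeneModels", function(x) x@cds)

#' @rdname accessors
#' @export
setGeneric("tss", function(x) standardGeneric("tss"))
#' @rdname accessors
#' @export
setMethod("tss", "GeneModels", function(x) {
  g <- x@genes
  pos <- ifelse(as.character(strand(g)) == "-", end(g), start(g))
  names(pos) <- geneIds(x)
  pos
})

#' @describeIn GeneModels subset by index, logical, or gene id
#' @param i index vector.
#' @export
setMethod("[", "GeneModels", function(x, i) {
  if (is.character(i)) i <- match(i, geneIds(x))
  genes <- x@genes[i]
  ids <- as.character(mcols(genes)$gene_id)
  cds <- x@cds[names(x@cds) %in% ids]
  new("GeneModels", genes = genes, exons = x@exons[i], cds = cds)
})

setMethod("show", "GeneModels", function(object) {
  cat(sprintf("GeneModels with %d gene(s) on %d contig(s)\n",
              length(object),
              length(unique(as.character(seqnames(object@genes))))))
  ncds <- length(object@cds)
  cat(sprintf("  exons: %d total; CDS annotated for %d gene(s)\n",
              sum(lengths(object@exons)), ncds))
  if (length(object)) {
    ids <- geneIds(object)
    cat("  gene ids: ", paste(utils::head(ids, 5), collapse = ", "),
        if (length(ids) > 5) ", ..." else "", "\n", sep = "")
  }
})

#' @describeIn ReconciledPeaks number of reconciled pairs
#' @param x,object a \code{ReconciledPeaks} object.
#' @export
setMethod("length", "ReconciledPeaks", function(x) length(x@representative))

#' @rdname accessors
#' @export
setGeneric("representative", function(x) standardGeneric("representative"))
#' @rdname accessors
#' @export
setMethod("representative", "ReconciledPeaks",
          function(x) x@representative)

#' @rdname accessors
#' @export
setGeneric("signalCenters", function(x) standardGeneric("signalCenters"))
#' @rdname accessors
#' @export
setMethod("signalCenters", "ReconciledPeaks", function(x) {
  mcols(x@representative)$center
})

#' @rdname accessors
#' @export
setGeneric("anchorDistances", function(x) standardGeneric("anchorDistances"))
#' @rdname accessors
#' @export
setMethod("anchorDistances", "ReconciledPeaks", function(x) {
  mcols(x@representative)$anchor_distance
})

#' Unmatched peaks from replicate reconciliation
#' @param x a \code{ReconciledPeaks} object.
#' @param which \code{"A"} or \code{"B"}.
#' @return \code{GRanges} of the peaks of that replicate left unpaired.
#' @export
setGeneric("unmatchedPeaks",
           function(x, which = c("A", "B")) standardGeneric("unmatchedPeaks"))
#' @rdname unmatchedPeaks
#' @export
setMethod("unmatchedPeaks", "ReconciledPeaks", function(x, which = c("A", "B")) {
  if (match.arg(which) == "A") x@unmatchedA else x@unmatchedB
})

setMethod("show", "ReconciledPeaks", function(object) {
  cat(sprintf(
    "ReconciledPeaks: %d reproducible pair(s) (max anchor distance %g bp)\n",
    length(object), object@maxDistance))
  cat(sprintf("  unmatched: %d in replicate A, %d in replicate B\n",
              length(object@unmatchedA), length(object@unmatchedB)))
  if (length(object)) {
    d <- anchorDistances(object)
    cat(sprintf("  anchor distance: median %g bp, max %g bp\n",
                stats::median(d), max(d)))
  }
})

setMethod("show", "TargetSetComparison", function(object) {
  f <- fractionsPercent(object)
  cat(sprintf("TargetSetComparison: |A| = %d, |B| = %d\n",
              length(object@setA), length(object@setB)))
  cat(sprintf("  common %d; A-specific %d (%d%%); B-specific %d (%d%%)\n",
              length(object@common),
              length(object@aSpecific), f[["a_specific"]],
              length(object@bSpecific), f[["b_specific"]]))
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf("  q thresholds: target %g, motif input %g\n",
              object@qTarget, object@qMotif))
  cat(sprintf("  reconciliation max distance: %g bp; target window: %g bp\n",
              object@maxDistance, object@targetWindow))
  cat(sprintf("  peak-center flank: %g bp; upstream windows: %s bp\n",
              object@flank,
              paste(object@upstreamLengths, collapse = ", ")))
  cat(sprintf("  motifs: %s\n",
              paste(sprintf("%s=%s", names(object@motifs), object@motifs),
                    collapse = ", ")))
  cat(sprintf("  lKC clusters: %s\n",
              paste(object@lkcClusters, collapse = ", ")))
  cat(sprintf(
    "  markers: min frac %g, min |log2FC| %g, alpha %g, adjust %s\n",
    object@markerMinFrac, object@markerMinEffect, object@markerAlpha,
    object@adjustMethod))
})
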