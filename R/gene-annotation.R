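#' Construct a GeneModels object
#'
#' @param genes \code{GRanges} with metadata columns \code{gene_id},
#'   \code{description}, \code{biotype}.
#' @param exons \code{GRangesList} parallel to \code{genes} (named by gene
#'   id); exons are sorted and reduced per gene.
#' @param cds optional \code{GRangesList} named by gene id.
#' @return a validated \code{\link{GeneModels}} object.
#' @export
GeneModels <- function(genes, exons, cds = GRangesList()) {
  exons <- GRangesList(lapply(exons, function(e) {
    BiocGenerics::sort(GenomicRanges::reduce(e))
  }))
  names(exons) <- mcols(genes)$gene_id
  if (length(cds)) {
    cds <- GRangesList(lapply(cds, function(e) {
      BiocGenerics::sort(GenomicRanges::reduce(e))
    }))
  }
  new("GeneModels", genes = genes, exons = exons, cds = cds)
}

#' Read a gene annotation into GeneModels
#'
#' Supports GFF3 (gene/mRNA/exon/CDS hierarchy; 1-based inclusive
#' coordinates) and BED12 (one line per gene with exon blocks; the thick
#' range, when a proper sub-range of the span, is taken as the CDS extent).
#' Multi-isoform genes collapse to their union span and union exon set.
#' Genes without explicit exon records get a single exon covering the span.
#'
#' @param path annotation file path.
#' @param dialect \code{"gff3"} or \code{"bed12"}.
#' @return a \code{\link{GeneModels}} object.
#' @export
readGeneAnnotation <- function(path, dialect = c("gff3", "bed12")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  if (dialect == "gff3") .readGff3Genes(path) else .readBed12Genes(path)
}

.attrOr <- function(mc, nm, default) {
  if (nm %in% colnames(mc)) {
    v <- as.character(mc[[nm]])
    ifelse(is.na(v) | !nzchar(v), default, v)
  } else rep(default, nrow(mc))
}

.readGff3Genes <- function(path) {
  ann <- rtracklayer::import(path, format = "gff3")
  type <- as.character(ann$type)
  geneRows <- ann[type %in% c("gene", "ncRNA_gene", "pseudogene")]
  if (!length(geneRows)) stopf("no gene records found in %s", path)
  gffIds <- as.character(geneRows$ID)
  ids <- .attrOr(mcols(geneRows), "gene_id", NA_character_)
  ids <- ifelse(is.na(ids), .attrOr(mcols(geneRows), "Name", NA_character_), ids)
  ids <- ifelse(is.na(ids), gffIds, ids)
  desc <- .attrOr(mcols(geneRows), "description", "")
  ## map transcript ID -> gene ID (one hop), genes map to themselves
  parentOf <- function(x) {
    p <- mcols(x)$Parent
    vapply(as.list(p), function(v) if (length(v)) v[[1L]] else NA_character_,
           character(1))
  }
  txRows <- ann[!type %in% c("gene", "ncRNA_gene", "pseudogene",
                             "exon", "CDS", "five_prime_UTR",
                             "three_prime_UTR", "region")]
  txParent <- parentOf(txRows)
  txIds <- as.character(txRows$ID)
  keep <- !is.na(txParent) & txParent %in% gffIds
  toGene <- stats::setNames(txParent[keep], txIds[keep])
  toGene <- c(toGene, stats::setNames(gffIds, gffIds))

  pickChildren <- function(what) {
    rows <- ann[type == what]
    if (!length(rows)) return(split(GRanges(), factor(character())))
    par <- parentOf(rows)
    gid <- unname(toGene[par])
    rows <- rows[!is.na(gid)]
    gid <- gid[!is.na(gid)]
    split(granges(rows), factor(gid, levels = gffIds))
  }
  exonsBy <- pickChildren("exon")
  cdsBy <- pickChildren("CDS")

  spans <- granges(geneRows)
  exons <- as.list(exonsBy)
  noEx <- lengths(exons) == 0L
  exons[noEx] <- as.list(split(spans[noEx], factor(seq_len(sum(noEx)))))
  exons <- GRangesList(exons)

  ## explicit validation with gene ids before class validity
  for (i in seq_along(exons)) {
    e <- exons[[i]]
    if (length(e) && (any(start(e) < start(spans)[i]) ||
                      any(end(e) > end(spans)[i])))
      stopf("exon outside parent gene span for gene %s in %s", ids[i], path)
  }

  hasCds <- lengths(cdsBy) > 0L
  biotype <- .attrOr(mcols(geneRows), "biotype",
                     .attrOr(mcols(geneRows), "gene_biotype", NA_character_))
  biotype <- ifelse(is.na(biotype),
                    ifelse(hasCds, "protein_coding", "other"), biotype)

  genes <- spans
  mcols(genes) <- DataFrame(gene_id = ids, description = desc,
                            biotype = biotype)
  cds <- cdsBy[hasCds]
  names(cds) <- ids[match(names(cds), gffIds)]
  names(exons) <- ids
  GeneModels(genes, exons, GRangesList(as.list(cds)))
}

.readBed12Genes <- function(path) {
  ann <- rtracklayer::import(path, format = "bed")
  if (!length(ann)) stopf("no records found in %s", path)
  ids <- as.character(ann$name)
  spans <- granges(ann)
  if (!"blocks" %in% colnames(mcols(ann)))
    stopf("BED input %s has no block structure (need BED12)", path)
  rel <- mcols(ann)$blocks  # block ranges relative to the line start
  exons <- GRangesList(lapply(seq_along(ann), function(i) {
    GRanges(seqnames(ann)[i],
            IRanges::shift(rel[[i]], start(ann)[i] - 1L),
            strand = strand(ann)[i])
  }))
  names(exons) <- ids
  cds <- list()
  if ("thick" %in% colnames(mcols(ann))) {
    thick <- mcols(ann)$thick
    for (i in seq_along(ann)) {
      th <- thick[i]
      proper <- width(th) > 0L &&
        (start(th) > start(ann)[i] || end(th) < end(ann)[i])
      if (proper) {
        thickGr <- GRanges(seqnames(ann)[i], th, strand = strand(ann)[i])
        ints <- GenomicRanges::intersect(exons[[i]], thickGr,
                                         ignore.strand = TRUE)
        if (length(ints)) cds[[ids[i]]] <- ints
      }
    }
  }
  genes <- spans
  mcols(genes) <- DataFrame(gene_id = ids, description = rep("", length(ann)),
                            biotype = ifelse(ids %in% names(cds),
                                             "protein_coding", "other"))
  GeneModels(genes, exons, GRangesList(cds))
}

#' Write GeneModels to GFF3 or BED12
#'
#' The GFF3 writer emits a gene/mRNA/exon/CDS hierarchy (one synthetic
#' transcript per gene carrying the union exon set); the BED12 writer emits
#' one line per gene with exon blocks and the CDS extent as the thick range.
#' Both round-trip through \code{\link{readGeneAnnotation}}.
#'
#' @param gm a \code{\link{GeneModels}} object.
#' @param path output path.
#' @param dialect \code{"gff3"} or \code{"bed12"}.
#' @export
writeGeneAnnotation <- function(gm, path, dialect = c("gff3", "bed12")) {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") .writeGff3Genes(gm, path) else .writeBed12Genes(gm, path)
  invisible(path)
}

.writeGff3Genes <- function(gm, path) {
  g <- geneRanges(gm)
  ids <- geneIds(gm)
  txIds <- paste0(ids, ".t1")
  rows <- list()
  geneGr <- g
  mcols(geneGr) <- DataFrame(type = "gene", ID = ids,
                             Name = ids,
                             description = mcols(g)$description,
                             biotype = mcols(g)$biotype,
                             Parent = CharacterList(vector("list", length(g))),
                             phase = NA_integer_)
  txGr <- g
  mcols(txGr) <- DataFrame(type = "mRNA", ID = txIds, Name = txIds,
                           description = NA_character_,
                           biotype = NA_character_,
                           Parent = CharacterList(as.list(ids)),
                           phase = NA_integer_)
  exn <- exonStructure(gm)
  exGr <- BiocGenerics::unlist(exn, use.names = TRUE)
  exParent <- txIds[match(names(exGr), ids)]
  mcols(exGr) <- DataFrame(type = "exon", ID = NA_character_,
                           Name = NA_character_, description = NA_character_,
                           biotype = NA_character_,
                           Parent = CharacterList(as.list(exParent)),
                           phase = NA_integer_)
  names(exGr) <- NULL
  parts <- list(geneGr, txGr, exGr)
  cds <- cdsStructure(gm)
  if (length(cds)) {
    cdGr <- BiocGenerics::unlist(cds, use.names = TRUE)
    cdParent <- txIds[match(names(cdGr), ids)]
    mcols(cdGr) <- DataFrame(type = "CDS", ID = NA_character_,
                             Name = NA_character_, description = NA_character_,
                             biotype = NA_character_,
                             Parent = CharacterList(as.list(cdParent)),
                             phase = 0L)
    names(cdGr) <- NULL
    parts <- c(parts, list(cdGr))
  }
  ann <- do.call(c, parts)
  ann <- BiocGenerics::sort(ann, ignore.strand = TRUE)
  rtracklayer::export(ann, path, format = "gff3")
}

.writeBed12Genes <- function(gm, path) {
  g <- geneRanges(gm)
  ids <- geneIds(gm)
  exn <- exonStructure(gm)
  cds <- cdsStructure(gm)
  lines <- vapply(seq_along(g), function(i) {
    e <- exn[[i]]
    chromStart <- start(g)[i] - 1L
    sizes <- paste0(paste(width(e), collapse = ","), ",")
    starts <- paste0(paste(start(e) - 1L - chromStart, collapse = ","), ",")
    id <- ids[i]
    if (id %in% names(cds)) {
      cd <- range(cds[[id]])
      thickStart <- start(cd) - 1L
      thickEnd <- end(cd)
    } else {
      thickStart <- thickEnd <- chromStart
    }
    strandChr <- as.character(strand(g))[i]
    if (strandChr == "*") strandChr <- "."
    paste(as.character(seqnames(g))[i], chromStart, end(g)[i], id, 0L,
          strandChr, thickStart, thickEnd, "0,0,0", length(e), sizes, starts,
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Untranslated regions of a gene
#'
#' Returns the exonic intervals 5' of the CDS start and 3' of the CDS end
#' (strand-aware), or \code{NULL} when the gene has no annotated CDS — UTR
#' position labels are only assigned where CDS records exist.
#'
#' @param gm a \code{\link{GeneModels}} object.
#' @param geneId a single gene id.
#' @return \code{NULL} or \code{list(utr5 = GRanges, utr3 = GRanges)}.
#' @export
utrRegions <- function(gm, geneId) {
  cds <- cdsStructure(gm)
  if (!geneId %in% names(cds)) return(NULL)
  i <- match(geneId, geneIds(gm))
  g <- geneRanges(gm)[i]
  e <- exonStructure(gm)[[i]]
  cd <- range(cds[[geneId]])
  chr <- as.character(seqnames(g))
  left <- if (start(cd) > start(g))
    GenomicRanges::intersect(e, GRanges(chr, IRanges(start(g), start(cd) - 1L)),
                             ignore.strand = TRUE) else GRanges()
  right <- if (end(cd) < end(g))
    GenomicRanges::intersect(e, GRanges(chr, IRanges(end(cd) + 1L, end(g))),
                             ignore.strand = TRUE) else GRanges()
  if (as.character(strand(g)) == "-") list(utr5 = right, utr3 = left)
  else list(utr5 = left, utr3 = right)
}
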