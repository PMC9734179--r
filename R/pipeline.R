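#' Create a pipeline configuration
#'
#' Defaults hold the analysis constants: target-calling q threshold 0.005,
#' motif-input q threshold 0.001, 1-kb replicate reconciliation bound,
#' 10-kb target window, 150-bp peak-center flank, 2-kb/10-kb upstream
#' windows, GAGA/GAG motif set, lKC clusters {1,2,6,7}, and the marker-test
#' parameters (expressed fraction 0.1, |log2FC| 0.25, alpha 0.05,
#' Bonferroni).
#'
#' @param qTarget,qMotif q-value thresholds in (0, 1].
#' @param maxDistance replicate reconciliation bound, bp.
#' @param targetWindow gene assignment window, bp.
#' @param flank peak-center half-window for motif input, bp.
#' @param upstreamLengths TSS-upstream window lengths, bp.
#' @param motifs named character vector of plain motifs.
#' @param lkcClusters cluster ids regarded as lKCs.
#' @param markerMinFrac,markerMinEffect,markerAlpha,adjustMethod marker-test
#'   parameters (see \code{\link{findMarkers}}).
#' @param seed integer seed used by the simulate stage.
#' @return a \code{\link{PipelineConfig}} object.
#' @export
pipelineConfig <- function(qTarget = 0.005, qMotif = 0.001,
                           maxDistance = 1000, targetWindow = 10000,
                           flank = 150, upstreamLengths = c(2000, 10000),
                           motifs = c(GAGA = "GAGA", GAG = "GAG"),
                           lkcClusters = c("1", "2", "6", "7"),
                           markerMinFrac = 0.1, markerMinEffect = 0.25,
                           markerAlpha = 0.05,
                           adjustMethod = c("bonferroni", "BH"),
                           seed = 1L) {
  new("PipelineConfig", qTarget = qTarget, qMotif = qMotif,
      maxDistance = maxDistance, targetWindow = targetWindow, flank = flank,
      upstreamLengths = upstreamLengths, motifs = motifs,
      lkcClusters = as.character(lkcClusters),
      markerMinFrac = markerMinFrac, markerMinEffect = markerMinEffect,
      markerAlpha = markerAlpha, adjustMethod = match.arg(adjustMethod),
      seed = as.numeric(seed))
}

.configAsList <- function(config) {
  sn <- methods::slotNames("PipelineConfig")
  stats::setNames(lapply(sn, function(s) {
    v <- methods::slot(config, s)
    if (s == "motifs") as.list(v) else v
  }), sn)
}

#' Read and write pipeline configurations as YAML
#'
#' The configuration round-trips exactly: writing and re-reading yields an
#' identical object.
#'
#' @param config a \code{\link{PipelineConfig}} object.
#' @param path YAML file path.
#' @return \code{readPipelineConfig}: a \code{PipelineConfig}.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(.configAsList(config), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- yaml::read_yaml(path)
  pipelineConfig(qTarget = x$qTarget, qMotif = x$qMotif,
                 maxDistance = x$maxDistance,
                 targetWindow = x$targetWindow, flank = x$flank,
                 upstreamLengths = unlist(x$upstreamLengths),
                 motifs = unlist(x$motifs),
                 lkcClusters = as.character(unlist(x$lkcClusters)),
                 markerMinFrac = x$markerMinFrac,
                 markerMinEffect = x$markerMinEffect,
                 markerAlpha = x$markerAlpha,
                 adjustMethod = x$adjustMethod, seed = x$seed)
}

## atomic write: run writer(tmp) then rename into place
.atomically <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  path
}

.writeTsv <- function(d, path) {
  .atomically(path, function(p)
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE))
}

## load two narrowPeak replicates, q-filter, reconcile
.loadReconcile <- function(inputs, config, qMax) {
  repA <- filterPeaksByQ(readNarrowPeak(inputs$repA), qMax)
  repB <- filterPeaksByQ(readNarrowPeak(inputs$repB), qMax)
  reconcileReplicates(repA, repB, maxDistance = config@maxDistance)
}

.reconciledTsv <- function(rec) {
  rep <- representative(rec)
  data.frame(contig = as.character(seqnames(rep)), start = start(rep),
             end = end(rep), name = mcols(rep)$name,
             center = mcols(rep)$center,
             fold_enrichment = mcols(rep)$signalValue,
             neg_log10_p = mcols(rep)$pValue,
             neg_log10_q = mcols(rep)$qValue,
             anchor_distance = mcols(rep)$anchor_distance,
             source = mcols(rep)$source, stringsAsFactors = FALSE)
}

#' Run one pipeline stage
#'
#' Dispatches the named stage on file inputs, writes its outputs plus a JSON
#' run manifest (configuration, input checksums, outputs, package version)
#' under \code{outdir}, and returns the output paths. Outputs are written
#' atomically (temp file + rename) under fixed names, and contain no
#' timestamps, so a rerun with identical configuration and inputs is
#' byte-identical.
#'
#' Stages and their inputs (named entries of \code{inputs}):
#' \describe{
#'   \item{simulate}{none; writes genome.fa, genes.gff3, repA/repB
#'     narrowPeak, sc_counts.tsv, sc_clusters.tsv, hits_a2b/b2a.tsv,
#'     truth.json, using \code{config@seed}.}
#'   \item{reconcile}{\code{repA}, \code{repB} (narrowPeak), optional
#'     \code{genome} (FASTA); writes reconciled.tsv and, with a genome,
#'     motif_input_windows.fa (q threshold \code{qMotif}, ±\code{flank} bp).}
#'   \item{targets}{\code{repA}, \code{repB}, \code{annotation} (GFF3);
#'     writes targets.tsv and report_top20.tsv.}
#'   \item{compare}{\code{targetsA}, \code{targetsB} (targets.tsv files);
#'     writes venn_summary.tsv.}
#'   \item{motif-count}{\code{genome}, \code{annotation}; writes
#'     motif_counts.tsv.}
#'   \item{rank}{\code{counts} (gene_id/count/length TSV); writes
#'     ranked_genes.tsv.}
#'   \item{markers}{\code{counts} (genes x cells TSV), \code{clusters}
#'     (cell/cluster TSV); writes markers.tsv.}
#'   \item{intersect}{\code{targets} (targets.tsv), \code{markers}
#'     (markers.tsv); writes candidates.tsv and breakdown.tsv.}
#'   \item{rbh}{\code{a2b}, \code{b2a} (hit TSVs); writes orthologs.tsv.}
#'   \item{report}{\code{dir} (a directory of stage artifacts); assembles
#'     report.txt from the TSVs already present, without recomputation.}
#' }
#'
#' @param stage stage name (see Details).
#' @param config a \code{\link{PipelineConfig}}.
#' @param inputs named list of input file paths.
#' @param outdir output directory (created if needed).
#' @return invisibly, a named character vector of output paths.
#' @export
runPipeline <- function(stage, config = pipelineConfig(), inputs = list(),
                        outdir = ".") {
  stage <- match.arg(stage, c("simulate", "reconcile", "targets", "compare",
                              "motif-count", "rank", "markers", "intersect",
                              "rbh", "report"))
  stopifnot(is(config, "PipelineConfig"))
  methods::validObject(config)
  for (nm in names(inputs)) {
    if (!file.exists(inputs[[nm]]))
      stopf("input '%s' not found: %s", nm, inputs[[nm]])
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(stage,
    simulate = .stageSimulate(config, outdir),
    reconcile = .stageReconcile(config, inputs, outdir),
    targets = .stageTargets(config, inputs, outdir),
    compare = .stageCompare(config, inputs, outdir),
    `motif-count` = .stageMotifCount(config, inputs, outdir),
    rank = .stageRank(config, inputs, outdir),
    markers = .stageMarkers(config, inputs, outdir),
    intersect = .stageIntersect(config, inputs, outdir),
    rbh = .stageRbh(config, inputs, outdir),
    report = .stageReport(config, inputs, outdir))
  manifest <- list(
    stage = stage,
    config = .configAsList(config),
    inputs = lapply(inputs, function(p)
      list(path = p,
           md5 = if (dir.exists(p)) NA else unname(tools::md5sum(p)))),
    outputs = as.list(out),
    package = "gagaTargets",
    version = as.character(utils::packageVersion("gagaTargets")))
  .atomically(file.path(outdir, paste0("manifest_", stage, ".json")),
              function(p) jsonlite::write_json(manifest, p,
                                               auto_unbox = TRUE, digits = NA))
  invisible(out)
}

.stageSimulate <- function(config, outdir) {
  seed <- as.integer(config@seed)
  contigs <- c(ctg1 = 300000L, ctg2 = 200000L)
  genome <- generateGenome(seed, contigs)
  genes <- generateGeneModels(seed + 1L, contigs, n = 30)
  pk <- generateReplicatePeaks(seed + 2L, contigs, nTrue = 20,
                               nNoisePerRep = 10)
  sc <- generateScCounts(seed + 3L, nClusters = 4, cellsPerCluster = 50,
                         nGenes = 200, markersPerCluster = 5, fold = 8,
                         clusterIds = config@lkcClusters)
  hits <- generateHitTables(seed + 4L, nA = 30, nB = 30, nTruePairs = 10)
  paths <- c(genome = file.path(outdir, "genome.fa"),
             annotation = file.path(outdir, "genes.gff3"),
             repA = file.path(outdir, "repA.narrowPeak"),
             repB = file.path(outdir, "repB.narrowPeak"),
             sc_counts = file.path(outdir, "sc_counts.tsv"),
             sc_clusters = file.path(outdir, "sc_clusters.tsv"),
             a2b = file.path(outdir, "hits_a2b.tsv"),
             b2a = file.path(outdir, "hits_b2a.tsv"),
             truth = file.path(outdir, "truth.json"))
  .atomically(paths[["genome"]], function(p)
    Biostrings::writeXStringSet(genome, p))
  .atomically(paths[["annotation"]], function(p)
    writeGeneAnnotation(genes, p, "gff3"))
  .atomically(paths[["repA"]], function(p) writeNarrowPeak(pk$repA, p))
  .atomically(paths[["repB"]], function(p) writeNarrowPeak(pk$repB, p))
  .writeTsv(data.frame(gene_id = rownames(sc$counts), sc$counts,
                       check.names = FALSE), paths[["sc_counts"]])
  .writeTsv(data.frame(cell = colnames(sc$counts), cluster = sc$clusters),
            paths[["sc_clusters"]])
  .writeTsv(hits$a2b, paths[["a2b"]])
  .writeTsv(hits$b2a, paths[["b2a"]])
  truth <- list(peaks = pk$truth, sc_markers = sc$truth,
                ortholog_pairs = hits$truth)
  .atomically(paths[["truth"]], function(p)
    jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA))
  paths
}

.stageReconcile <- function(config, inputs, outdir) {
  rec <- .loadReconcile(inputs, config, config@qTarget)
  paths <- c(reconciled = file.path(outdir, "reconciled.tsv"))
  .writeTsv(.reconciledTsv(rec), paths[["reconciled"]])
  if (!is.null(inputs$genome)) {
    recMotif <- .loadReconcile(inputs, config, config@qMotif)
    genome <- Biostrings::readDNAStringSet(inputs$genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    win <- extractPeakWindow(genome, recMotif, flank = config@flank)
    paths <- c(paths, windows = file.path(outdir, "motif_input_windows.fa"))
    .atomically(paths[["windows"]], function(p)
      Biostrings::writeXStringSet(win, p))
  }
  paths
}

.stageTargets <- function(config, inputs, outdir) {
  rec <- .loadReconcile(inputs, config, config@qTarget)
  genes <- readGeneAnnotation(inputs$annotation, "gff3")
  asg <- assignTargets(rec, genes, window = config@targetWindow)
  paths <- c(targets = file.path(outdir, "targets.tsv"),
             report = file.path(outdir, "report_top20.tsv"))
  .writeTsv(asg, paths[["targets"]])
  .writeTsv(rankSignalReport(asg, topN = 20), paths[["report"]])
  paths
}

.stageCompare <- function(config, inputs, outdir) {
  geneSet <- function(p) {
    d <- utils::read.delim(p, stringsAsFactors = FALSE)
    unique(stats::na.omit(d$gene_id))
  }
  cmp <- compareTargetSets(geneSet(inputs$targetsA), geneSet(inputs$targetsB))
  pct <- fractionsPercent(cmp)
  d <- data.frame(
    set = c("A", "B", "common", "A_specific", "B_specific"),
    n = c(length(cmp@setA), length(cmp@setB), length(commonIds(cmp)),
          length(specificIds(cmp, "A")), length(specificIds(cmp, "B"))),
    percent = c(100, 100, pct[["common_in_a"]], pct[["a_specific"]],
                pct[["b_specific"]]))
  paths <- c(venn = file.path(outdir, "venn_summary.tsv"))
  .writeTsv(d, paths[["venn"]])
  paths
}

.stageMotifCount <- function(config, inputs, outdir) {
  genome <- Biostrings::readDNAStringSet(inputs$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genes <- readGeneAnnotation(inputs$annotation, "gff3")
  ups <- lapply(config@upstreamLengths, function(L)
    extractUpstream(genes, genome, length = L))
  up <- do.call(c, ups)
  tbl <- speciesMotifTable(up, motifs = config@motifs,
                           windows = config@upstreamLengths)
  paths <- c(counts = file.path(outdir, "motif_counts.tsv"))
  .writeTsv(tbl, paths[["counts"]])
  paths
}

.stageRank <- function(config, inputs, outdir) {
  d <- readGeneCounts(inputs$counts)
  paths <- c(ranked = file.path(outdir, "ranked_genes.tsv"))
  .writeTsv(rankByLengthNormalized(d, topN = 40), paths[["ranked"]])
  paths
}

.stageMarkers <- function(config, inputs, outdir) {
  m <- readCountMatrix(inputs$counts)
  lab <- readClusterLabels(inputs$clusters)
  clusters <- lab$cluster[match(colnames(m), lab$cell)]
  mk <- findMarkers(m, clusters, minFrac = config@markerMinFrac,
                    minEffect = config@markerMinEffect,
                    alpha = config@markerAlpha,
                    adjust = config@adjustMethod)
  paths <- c(markers = file.path(outdir, "markers.tsv"))
  .writeTsv(mk, paths[["markers"]])
  paths
}

.stageIntersect <- function(config, inputs, outdir) {
  tg <- utils::read.delim(inputs$targets, stringsAsFactors = FALSE)
  mk <- utils::read.delim(inputs$markers, stringsAsFactors = FALSE,
                          colClasses = c(cluster = "character"))
  res <- intersectTargetsWithMarkers(stats::na.omit(tg$gene_id), mk,
                                     lkcClusters = config@lkcClusters)
  paths <- c(candidates = file.path(outdir, "candidates.tsv"),
             breakdown = file.path(outdir, "breakdown.tsv"))
  .writeTsv(res$candidates, paths[["candidates"]])
  .writeTsv(data.frame(bucket = names(res$buckets),
                       n = as.integer(res$buckets)), paths[["breakdown"]])
  paths
}

.stageRbh <- function(config, inputs, outdir) {
  pairs <- reciprocalBestHits(readHitTable(inputs$a2b),
                              readHitTable(inputs$b2a))
  paths <- c(orthologs = file.path(outdir, "orthologs.tsv"))
  .writeTsv(pairs, paths[["orthologs"]])
  paths
}

.stageReport <- function(config, inputs, outdir) {
  dirIn <- inputs$dir
  lines <- c("gagaTargets pipeline report", "")
  grab <- function(f) file.path(dirIn, f)
  if (file.exists(grab("report_top20.tsv"))) {
    d <- utils::read.delim(grab("report_top20.tsv"))
    lines <- c(lines, sprintf("Top signals table: %d row(s)", nrow(d)))
  }
  if (file.exists(grab("venn_summary.tsv"))) {
    d <- utils::read.delim(grab("venn_summary.tsv"))
    lines <- c(lines, "Target set comparison:",
               sprintf("  %s: n=%d (%g%%)", d$set, d$n, d$percent))
  }
  if (file.exists(grab("breakdown.tsv"))) {
    d <- utils::read.delim(grab("breakdown.tsv"))
    lines <- c(lines, "Candidate lKC-cluster breakdown:",
               sprintf("  markers of %s cluster(s): %d", d$bucket, d$n))
  }
  if (file.exists(grab("motif_counts.tsv"))) {
    d <- utils::read.delim(grab("motif_counts.tsv"))
    lines <- c(lines, sprintf("Motif count table: %d row(s)", nrow(d)))
  }
  paths <- c(report = file.path(outdir, "report.txt"))
  .atomically(paths[["report"]], function(p) writeLines(lines, p))
  paths
}
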