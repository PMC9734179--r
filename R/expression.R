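#' Rank genes by length-normalised expression
#'
#' Divides each gene's raw count by its gene length and ranks genes by the
#' quotient, descending — the simple normalisation used to list the most
#' highly expressed genes in a bulk count table. Ties are broken by raw
#' count descending, then gene id lexicographically, so the ranking is
#' invariant to input row order. Genes without a length are excluded with a
#' warning reporting how many were dropped.
#'
#' @param counts named numeric vector of raw counts, or a \code{data.frame}
#'   with columns \code{gene_id}, \code{count} and (optionally)
#'   \code{length}.
#' @param lengths named numeric vector of gene lengths in bp (ignored when
#'   \code{counts} is a data frame carrying lengths).
#' @param topN how many top genes to return (default 40); \code{Inf} for all.
#' @return \code{data.frame} with columns \code{gene_id}, \code{count},
#'   \code{length}, \code{normalized}, \code{rank} (1..N, no gaps).
#' @export
rankByLengthNormalized <- function(counts, lengths = NULL, topN = 40) {
  if (is.data.frame(counts)) {
    if (!all(c("gene_id", "count") %in% colnames(counts)))
      stopf("count table needs 'gene_id' and 'count' columns")
    d <- data.frame(gene_id = as.character(counts$gene_id),
                    count = as.numeric(counts$count),
                    stringsAsFactors = FALSE)
    d$length <- if ("length" %in% colnames(counts))
      as.numeric(counts$length)
    else as.numeric(lengths[d$gene_id])
  } else {
    d <- data.frame(gene_id = names(counts), count = as.numeric(counts),
                    stringsAsFactors = FALSE)
    d$length <- as.numeric(lengths[d$gene_id])
  }
  if (any(d$count < 0, na.rm = TRUE)) stopf("negative counts are not allowed")
  bad <- is.na(d$length)
  if (any(bad)) {
    warnf("%d gene(s) without a length were excluded from the ranking",
          sum(bad))
    d <- d[!bad, , drop = FALSE]
  }
  if (any(d$length <= 0)) stopf("gene lengths must be positive")
  d$normalized <- d$count / d$length
  d <- d[order(-d$normalized, -d$count, d$gene_id), , drop = FALSE]
  d$rank <- seq_len(nrow(d))
  rownames(d) <- NULL
  utils::head(d, topN)
}

## Vectorised two-sided Wilcoxon rank-sum test, one row at a time against a
## fixed group split: normal approximation with tie correction and
## continuity correction (the standard large-sample form; cross-checked
## against stats::wilcox.test in the test suite).
.rowWilcox <- function(mat, inGroup) {
  n1 <- sum(inGroup); n2 <- sum(!inGroup); n <- n1 + n2
  apply(mat, 1L, function(v) {
    r <- rank(v)
    W <- sum(r[inGroup]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    ties <- table(v)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  })
}

#' One-vs-rest cluster marker detection
#'
#' For each cluster, tests every gene for differential expression between
#' the cluster's cells and all other cells using a two-sided Wilcoxon
#' rank-sum test on log-normalised expression (counts per 10,000 per cell,
#' then \code{log1p}). Genes are pre-filtered to those expressed in at least
#' \code{minFrac} of the cluster's cells with \eqn{|\log_2} fold change| of
#' at least \code{minEffect} (cluster mean vs rest mean of the normalised
#' values, pseudocount 1). P-values are adjusted over all genes in the
#' matrix (Bonferroni by default, Benjamini-Hochberg optional); records
#' with adjusted p below \code{alpha} are flagged as markers.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), cells
#'   in columns.
#' @param clusters vector of cluster labels, one per cell. Clusters with
#'   fewer than 3 cells are excluded with a warning; at least 2 clusters
#'   must remain.
#' @param minFrac minimum expressed fraction within the cluster (default 0.1).
#' @param minEffect minimum absolute log2 fold change (default 0.25).
#' @param alpha adjusted-p significance level (default 0.05).
#' @param adjust \code{"bonferroni"} (default) or \code{"BH"}.
#' @return \code{data.frame} with columns \code{gene_id}, \code{cluster},
#'   \code{effect}, \code{p}, \code{p_adj}, \code{frac_in}, \code{frac_out},
#'   \code{is_marker} — one row per (cluster, tested gene).
#' @export
findMarkers <- function(counts, clusters, minFrac = 0.1, minEffect = 0.25,
                        alpha = 0.05, adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  checkProb(alpha, "alpha")
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (length(clusters) != ncol(counts))
    stopf("one cluster label per cell is required (%d labels, %d cells)",
          length(clusters), ncol(counts))
  if (any(counts < 0)) stopf("negative counts are not allowed")
  clusters <- as.character(clusters)
  sizes <- table(clusters)
  small <- names(sizes)[sizes < 3L]
  if (length(small)) {
    warnf("excluding cluster(s) with fewer than 3 cells: %s",
          paste(small, collapse = ", "))
    keep <- !clusters %in% small
    counts <- counts[, keep, drop = FALSE]
    clusters <- clusters[keep]
  }
  if (length(unique(clusters)) < 2L)
    stopf("marker detection needs at least 2 clusters with >= 3 cells")
  libSize <- colSums(counts)
  libSize[libSize == 0] <- 1
  norm <- sweep(counts, 2L, libSize, "/") * 1e4
  logNorm <- log1p(norm)
  nGenes <- nrow(counts)
  out <- list()
  for (cl in sort(unique(clusters))) {
    inGroup <- clusters == cl
    fracIn <- rowMeans(counts[, inGroup, drop = FALSE] > 0)
    fracOut <- rowMeans(counts[, !inGroup, drop = FALSE] > 0)
    meanIn <- rowMeans(norm[, inGroup, drop = FALSE])
    meanOut <- rowMeans(norm[, !inGroup, drop = FALSE])
    effect <- log2((meanIn + 1) / (meanOut + 1))
    tested <- fracIn >= minFrac & abs(effect) >= minEffect
    if (!any(tested)) next
    p <- .rowWilcox(logNorm[tested, , drop = FALSE], inGroup)
    pAdj <- stats::p.adjust(p, method = adjust, n = nGenes)
    out[[cl]] <- data.frame(
      gene_id = rownames(counts)[tested], cluster = cl,
      effect = effect[tested], p = p, p_adj = pAdj,
      frac_in = fracIn[tested], frac_out = fracOut[tested],
      is_marker = pAdj < alpha, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(), cluster = character(),
                      effect = numeric(), p = numeric(), p_adj = numeric(),
                      frac_in = numeric(), frac_out = numeric(),
                      is_marker = logical(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Intersect binding targets with lKC cluster markers
#'
#' Candidate genes are the binding targets that are markers — with higher
#' expression, i.e. positive effect — in at least one of the large-type
#' Kenyon cell clusters. Each candidate is annotated with
#' the number of lKC clusters in which it is a marker, and the candidates
#' are partitioned into buckets: markers of 3 or more of the clusters, of
#' exactly 2, and of exactly 1.
#'
#' @param targets character vector of target gene ids.
#' @param markers marker table from \code{\link{findMarkers}}.
#' @param lkcClusters cluster ids regarded as lKCs (default
#'   \code{c("1", "2", "6", "7")}); must all be present among the marker
#'   table's clusters.
#' @param onlyPositive count only markers with positive effect (default
#'   \code{TRUE}): a gene upregulated in one cluster also tests significant
#'   with negative effect in the others, which must not make it their
#'   marker.
#' @return list with \code{candidates} (\code{data.frame} of \code{gene_id},
#'   \code{n_clusters}, \code{clusters}) and \code{buckets} (named integer
#'   vector \code{"3+"}, \code{"2"}, \code{"1"}; sums to the candidate
#'   count).
#' @export
intersectTargetsWithMarkers <- function(targets, markers,
                                        lkcClusters = c("1", "2", "6", "7"),
                                        onlyPositive = TRUE) {
  lkcClusters <- as.character(lkcClusters)
  observed <- unique(as.character(markers$cluster))
  miss <- setdiff(lkcClusters, observed)
  if (length(miss))
    stopf("lKC cluster id(s) absent from the marker table: %s",
          paste(miss, collapse = ", "))
  mk <- markers[markers$is_marker &
                  as.character(markers$cluster) %in% lkcClusters &
                  (!onlyPositive | markers$effect > 0), ,
                drop = FALSE]
  targets <- unique(as.character(targets))
  mk <- mk[mk$gene_id %in% targets, , drop = FALSE]
  byGene <- split(as.character(mk$cluster), mk$gene_id)
  byGene <- lapply(byGene, unique)
  cand <- data.frame(gene_id = names(byGene),
                     n_clusters = lengths(byGene),
                     clusters = vapply(byGene, function(x)
                       paste(sort(x), collapse = ","), character(1)),
                     stringsAsFactors = FALSE)
  cand <- cand[order(-cand$n_clusters, cand$gene_id), , drop = FALSE]
  rownames(cand) <- NULL
  buckets <- c("3+" = sum(cand$n_clusters >= 3L),
               "2" = sum(cand$n_clusters == 2L),
               "1" = sum(cand$n_clusters == 1L))
  list(candidates = cand, buckets = buckets)
}

#' Resolve reciprocal-best-hit orthologs from pairwise hit tables
#'
#' The best hit of each query is its maximum-bitscore subject (ties broken
#' by smaller e-value, then lexicographic subject id); a pair (a, b) is an
#' ortholog pair when a's best hit is b and b's best hit is a. Queries with
#' no hits are dropped; duplicated (query, subject) rows keep the
#' best-scoring one, with a warning.
#'
#' @param a2b,b2a \code{data.frame}s with columns \code{qseqid},
#'   \code{sseqid}, \code{bitscore}, \code{evalue} (BLAST outfmt-6-like).
#' @return \code{data.frame} with columns \code{id_a}, \code{id_b},
#'   \code{score_a2b}, \code{score_b2a}, sorted by \code{id_a}.
#' @export
reciprocalBestHits <- function(a2b, b2a) {
  best <- function(tab, label) {
    need <- c("qseqid", "sseqid", "bitscore", "evalue")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
      stopf("hit table %s lacks column(s): %s", label,
            paste(miss, collapse = ", "))
    if (any(tab$evalue < 0)) stopf("negative e-value in table %s", label)
    tab <- tab[order(tab$qseqid, -tab$bitscore, tab$evalue, tab$sseqid), ,
               drop = FALSE]
    dup <- duplicated(tab[c("qseqid", "sseqid")])
    if (any(dup)) {
      warnf("%d duplicated (query, subject) row(s) in table %s; keeping the best",
            sum(dup), label)
      tab <- tab[!dup, , drop = FALSE]
    }
    tab[!duplicated(tab$qseqid), , drop = FALSE]
  }
  bA <- best(a2b, "a2b")
  bB <- best(b2a, "b2a")
  bestOfB <- stats::setNames(as.character(bB$sseqid), bB$qseqid)
  mutual <- !is.na(bestOfB[as.character(bA$sseqid)]) &
    bestOfB[as.character(bA$sseqid)] == as.character(bA$qseqid)
  mutual[is.na(mutual)] <- FALSE
  pairs <- bA[mutual, , drop = FALSE]
  out <- data.frame(
    id_a = as.character(pairs$qseqid), id_b = as.character(pairs$sseqid),
    score_a2b = pairs$bitscore,
    score_b2a = bB$bitscore[match(pairs$sseqid, bB$qseqid)],
    stringsAsFactors = FALSE)
  out <- out[order(out$id_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tabular readers for expression and homology inputs
#'
#' Thin readers for the TSV formats the pipeline consumes: a gene-level
#' count table with lengths (\code{gene_id}, \code{count}, \code{length}),
#' a genes-by-cells count matrix (first column = gene id, header = cell
#' ids), per-cell cluster labels (\code{cell}, \code{cluster}), and a
#' BLAST outfmt-6-like hit table (\code{qseqid}, \code{sseqid},
#' \code{bitscore}, \code{evalue}; headerless files are accepted when they
#' have exactly these 4 columns).
#'
#' @param path file path.
#' @return a \code{data.frame} (or matrix for \code{readCountMatrix}).
#' @name tabular-readers
NULL

#' @rdname tabular-readers
#' @export
readGeneCounts <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "count"), colnames(d))
  if (length(miss))
    stopf("gene count table %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  d
}

#' @rdname tabular-readers
#' @export
readCountMatrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  storage.mode(m) <- "numeric"
  if (any(m < 0)) stopf("negative counts in %s", path)
  m
}

#' @rdname tabular-readers
#' @export
readClusterLabels <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  miss <- setdiff(c("cell", "cluster"), colnames(d))
  if (length(miss))
    stopf("cluster label table %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  d
}

#' @rdname tabular-readers
#' @export
readHitTable <- function(path) {
  head1 <- utils::read.delim(path, nrows = 1L, header = FALSE,
                             stringsAsFactors = FALSE)
  hasHeader <- is.character(head1[[3L]])
  d <- utils::read.delim(path, header = hasHeader, stringsAsFactors = FALSE)
  if (!hasHeader) {
    if (ncol(d) != 4L)
      stopf("headerless hit table %s must have exactly 4 columns", path)
    colnames(d) <- c("qseqid", "sseqid", "bitscore", "evalue")
  }
  d
}
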