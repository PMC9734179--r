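# gagaTargets

Downstream analysis of transcription-factor ChIP-seq in the honey bee
(*Apis mellifera*) mushroom body, and comparative analysis of GA-rich
promoter motifs across hymenopteran species.

Mushroom bodies are the insect brain's higher-order learning and memory
centers. The transcription factor Mblk-1/E93 is preferentially expressed in
their large-type Kenyon cells (lKCs) and binds GA-rich motifs (GAGA, GAG).
This package implements the bespoke computations needed to go from called
ChIP-seq peaks to a catalog of candidate target genes and to a cross-species
comparison of motif accumulation — for analysts who have run a standard
aligner + peak caller (e.g. Bowtie2 + MACS2) and want the study-specific
downstream steps as tested, reusable functions.

## What it computes

* **Replicate reconciliation.** Peaks from two biological replicates,
  q-filtered at a threshold *q*\* (default 0.005; 0.001 for motif-discovery
  input), are reproducible when their anchors (summit, else midpoint) lie
  within 1 kb: the package returns the maximum one-to-one matching
  minimising total anchor distance, computed exactly per contig
  (`reconcileReplicates`). Each reproducible signal carries the member with
  the larger −log₁₀ *q* as representative and the anchor midpoint as center.
* **Target assignment.** A gene is a candidate target of a signal when the
  representative interval lies within *w* = 10 kb of the gene span
  (`assignTargets`); the signal center is classified against the gene
  structure as 5′UTR / 3′UTR / Exon / Intron / Upstream / Downstream
  (`classifyPosition`), and top signals are reported Table-style with
  side-numbered multi-gene rows (`rankSignalReport`). Condition-specific
  target catalogs are compared by exact set algebra (`compareTargetSets`).
* **Motif input and counting.** ±150 bp windows around signal centers for
  MEME-ChIP-style discovery (`extractPeakWindow`); strand-aware TSS-upstream
  windows of 2 kb / 10 kb (`extractUpstream`); and overlap-allowed motif
  counting (`countOverlapping`): every start position counts, so `GAGA`
  contains one GAGA and one GAG, and `GAGAG` one GAGA and two GAGs.
  `speciesMotifTable` builds the per-species GAGA/GAG accumulation table.
* **Expression integration.** Length-normalised ranking of bulk counts
  (count / gene length, top-40 display; `rankByLengthNormalized`);
  one-vs-rest Wilcoxon rank-sum cluster markers on log CP10K expression with
  Bonferroni adjustment and adjusted *p* < 0.05 (`findMarkers`);
  intersection of targets with lKC-cluster markers into 3+/2/1-cluster
  buckets (`intersectTargetsWithMarkers`); and reciprocal-best-hit ortholog
  assignment from BLAST-style hit tables (`reciprocalBestHits`).
* **Synthetic data.** Seeded generators (`generateGenome`,
  `generateGeneModels`, `generateReplicatePeaks`, `plantUpstreamMotifs`,
  `generateScCounts`, `generateHitTables`) emulate every input with planted
  ground truth, so the whole pipeline is verifiable without downloads.
* **Orchestration.** `pipelineConfig()` holds the analysis constants (YAML
  round-trip), and `runPipeline()` runs named stages on files, writing fixed
  outputs plus a JSON manifest; `inst/scripts/run_pipeline.R` is a thin
  shell wrapper.

## Worked example

```r
library(gagaTargets)

contigs <- c(ctg1 = 300000L, ctg2 = 200000L)
genome <- generateGenome(1, contigs)
genes  <- generateGeneModels(2, contigs, n = 20)
peaks  <- generateReplicatePeaks(3, contigs, nTrue = 12, nNoisePerRep = 5)

repA <- filterPeaksByQ(peaks$repA, qMax = 0.005)
repB <- filterPeaksByQ(peaks$repB, qMax = 0.005)
rec  <- reconcileReplicates(repA, repB, maxDistance = 1000)
rec
#> ReconciledPeaks: 12 reproducible pair(s) (max anchor distance 1000 bp)
#>   unmatched: 5 in replicate A, 5 in replicate B
#>   anchor distance: median 112 bp, max 192 bp
```

The 12 planted true peaks are recovered as reproducible pairs; the 5
replicate-specific noise peaks per replicate stay unmatched. Assigning
targets and ranking the strongest signals:

```r
asg <- assignTargets(rec, genes, window = 10000)
head(rankSignalReport(asg, topN = 3))
#>   gene_no   gene_id      description fold_enrichment neg_log10_q   position
#> 1       1      <NA>             <NA>         8.83927    37.39671       <NA>
#> 2     2-1 LOC100007 synthetic gene 7         8.03714    37.39534   Upstream
#> 3     2-2 LOC100008 synthetic gene 8              NA          NA       Exon
#> 4     2-3 LOC100009 synthetic gene 9              NA          NA Downstream
#> 5       3      <NA>             <NA>         8.43919    36.40629       <NA>
```

Signal 1 has no gene within ±10 kb (an explicit no-gene row, as in a
top-signals table); signal 2 has three genes in range, expanded to
side-numbered rows with its statistics printed once. Motif-discovery input
and upstream motif counts:

```r
win <- extractPeakWindow(genome, rec, flank = 150)   # 300-bp MEME-ChIP input
win[1]
#> DNAStringSet object of length 1:
#>     width seq                                           names
#> [1]   300 TTACTTCATTCTCTTAGTTACT...ATCTTATTGCTACCCT ctg1:41131-41430

up <- extractUpstream(genes, genome, length = 2000)  # TSS-upstream, 5'->3'
countOverlapping(as.character(up[[1]]), "GAG")
#> [1] 14
```

## Scope

Read alignment, peak calling, de novo motif discovery (MEME/DREME),
single-cell normalisation/clustering, and GO enrichment are consumed as
inputs or left to the dedicated external tools; this package covers the
analysis between those steps. See `vignettes/gagaTargets-methods.Rmd` for
the statistical details, parameter choices, and limitations.
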