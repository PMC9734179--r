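---
title: "Methods and design of gagaTargets"
author: "gagaTargets authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of gagaTargets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(gagaTargets))
```

# Overview

gagaTargets covers the downstream computations of a transcription-factor
ChIP-seq study in the honey bee mushroom body: reconciling peak calls from
two biological replicates, assigning reproducible binding signals to
candidate target genes, preparing motif-discovery input, counting GA-rich
motifs in TSS-upstream windows across species, and integrating binding
targets with bulk and single-cell expression. This vignette documents the
statistical procedures, the parameters that matter, the numerical
conventions, and the design choices that were genuinely open.

# Coordinates and file formats

All genomic intervals are held as `GRanges` (1-based, closed), the standard
Bioconductor convention. Conversions happen exactly once, at I/O
boundaries: narrowPeak/BED inputs (0-based, half-open) are shifted on read
and shifted back on write, GFF3 and region strings (1-based, inclusive)
map directly. The observable conventions are fixed by tests: a region
string `contig:first-last` spans `last − first + 1` bases and round-trips
exactly; abutting intervals have overlap 0 and gap distance 0; narrowPeak
round-trips preserve every field, including the `-1` summit sentinel
(represented as `NA` internally).

Multi-isoform genes collapse to their union span and union exon set,
because binding signals are annotated per gene, not per transcript; the TSS
is the span start on `+` and the span end on `-`, i.e. the 5′-most isoform
start. Overlapping genes are all retained — no winner is chosen when
several genes cover a signal.

# Replicate reconciliation

Two peaks, one per replicate on the same contig, are reproducible when
their anchors lie within `maxDistance` bp (default 1000, the within-1-kb
rule; the bound is inclusive). Choices made here:

* **Anchor.** The reported summit when present, else the interval
  midpoint. Summits are the peak caller's best estimate of the binding
  position; midpoint anchoring is available via `useSummit = FALSE`.
* **Matching objective.** Among eligible pairings, the maximum-cardinality
  one-to-one matching that minimises the total anchor distance. A greedy
  nearest-first matching is not order-stable on crowded loci; the package
  instead computes the exact optimum with a dynamic program over
  anchor-sorted peaks. For absolute distances on a line an optimal matching
  is non-crossing (uncrossing two matched pairs never increases the total
  distance and preserves eligibility), so the DP is exact; peaks further
  than `maxDistance` from every opposite peak split the problem into small
  independent blocks. The test suite checks the result against exhaustive
  assignment enumeration on instances up to 15 × 15.
* **Ties.** Backtracking prefers matching over skipping and otherwise
  advances the side with the smaller anchor, which makes the result
  deterministic and symmetric in the replicate roles.
* **Representative and center.** Each pair's representative is the member
  with the larger −log₁₀ *q* (replicate A on an exact tie), since top-signal
  tables rank by the lowest q-values and report one enrichment/q per
  signal. The signal center is the midpoint (floor) of the two anchors.

q-value filtering happens before matching: thresholds are supplied on the
q scale (0.005 for target calling, 0.001 for motif input) and converted to
−log₁₀ once, at filter time; scores are stored exactly as the caller
printed them.

# Target assignment and position labels

A (signal, gene) pair qualifies when the representative interval lies
within `window` bp (default 10 000) of the gene span — equivalently, the
interval overlaps the span extended by `window` on both sides, inclusive at
exactly `window`. Qualification uses the whole interval ("is it a
target"), while the positional label uses the signal center ("where is
it"): inside the span the priority is 5′UTR/3′UTR (only where CDS records
exist) over Exon over Intron; outside, Upstream is the TSS side given the
gene's strand. Unstranded genes are labelled as `+` with a warning. A
summit/center-based qualification mode (`measure = "center"`) is provided
since the measuring point is a convention, not a fact of the data.

Signals with no gene in range produce an explicit no-gene row, and signals
with several genes expand to side-numbered rows (`2-1`, `2-2`, ...) in
`rankSignalReport`, which orders by −log₁₀ *q* descending with fold
enrichment, then contig and coordinate, as deterministic tie-breaks.

Set comparisons (`compareTargetSets`) are exact set algebra on unique gene
ids. Displayed percentages round half-up to integers (`fractionsPercent`),
so 138/263 prints as 52%.

# Motif counting and upstream windows

`countOverlapping` counts every start position at which the motif occurs,
so overlapping occurrences all count — `GAGAG` contains one GAGA and two
GAGs. `N` never matches. The counter is property-tested against a naive
every-position oracle and against `Biostrings::countPattern`.

Upstream windows (`extractUpstream`) are the `length` bases immediately 5′
of the TSS, reverse-complemented for minus-strand genes so motifs are
counted on the gene-sense strand; windows clip at contig ends with a flag
and report their effective length. Counting is single-stranded by default —
the convention matches upstream flanks as served by sequence databases —
with a both-strands mode (`scanMotif(..., countBothStrands = TRUE)`) that
can only add matches. Motif specifications accept IUPAC codes and one
parenthesised optional base: `AT(C)TTTGTA` expands to `ATCTTTGTA` and
`ATTTTGTA`; which exact regular expression a discovery tool used is not
recoverable, so the optional-base reading is the package's convention.
`speciesMotifTable` reports the full subject × window × motif
cross-product, flagging missing window records as absent rather than zero.

# Expression integration

* **Length-normalised ranking.** Raw count divided by gene length, ranked
  descending; ties break by raw count then gene id, making the ranking
  invariant to input order. "Gene length" is taken from the supplied table;
  when deriving it from annotation, union-exon length is the natural choice
  for coding genes, but the genomic span is accepted — which length
  produced any given published ranking is generally unstated, so both are
  possible inputs.
* **Cluster markers.** One-vs-rest two-sided Wilcoxon rank-sum tests per
  gene on log1p counts-per-10k expression. This is a deliberate
  simplification of variance-stabilising normalisations used by single-cell
  toolkits: the rank-sum test depends only on within-gene orderings, which
  CP10K preserves. Genes enter testing when expressed in ≥ `minFrac` (0.1)
  of the cluster's cells with |log₂ fold change| ≥ `minEffect` (0.25),
  where the effect is the log₂ ratio of cluster to rest means of normalised
  expression with pseudocount 1. P-values are Bonferroni-adjusted over all
  genes in the matrix (the convention of the common single-cell marker
  tools; Benjamini–Hochberg is available), and markers are records with
  adjusted p below `alpha` (0.05). The test statistic uses the
  large-sample normal approximation with tie and continuity correction —
  the standard form for count data, verified against `stats::wilcox.test`
  — implemented vectorised because the power and null simulations run
  thousands of gene-level tests. Clusters with fewer than 3 cells are
  excluded with a warning.
* **Candidate intersection.** Candidates are targets that are markers with
  *positive* effect in ≥ 1 lKC cluster (default clusters 1, 2, 6, 7):
  a gene upregulated in one cluster is typically also "significant" with
  negative effect in the others, and counting those would corrupt the
  3+/2/1-cluster buckets. The buckets partition the candidate set by
  construction.
* **Reciprocal best hits.** Per query, the best hit is the maximum
  bitscore, ties broken by smaller e-value then lexicographic subject id;
  a pair is emitted when each member is the other's best. Duplicated
  (query, subject) rows keep the best-scoring row with a warning; queries
  without hits are dropped. The operation is symmetric in the table roles.

# Synthetic data: what it emulates, and what it does not

Every generator is a pure function of `(seed, parameters)` — reruns are
byte-identical and the caller's RNG state is untouched.

* Genomes are i.i.d. nucleotide sequences at fixed GC (default 0.35,
  AT-rich as in insect genomes). No repeats, assembly gaps, or isochores.
* Replicate peaks plant true anchors (≥ 5 kb apart) jittered independently
  per replicate (Gaussian, SD 100 bp, |shift| capped at 500 bp so pairs stay
  within 1 kb) plus replicate-specific noise peaks ≥ 2.5 kb from every true
  anchor and from each other, so reconciliation recovery is exact by
  construction. Scores are internally consistent (−log₁₀ q ≤ −log₁₀ p) and
  printed at 5 decimals as a caller would. Near-miss ambiguity (noise at
  1–2 kb) is deliberately excluded from the recovery fixtures; the matching
  itself is stress-tested separately against exhaustive enumeration.
* Motif planting writes GAGA/GAG instances at random non-adjacent offsets
  in a TSS-upstream window, then *recounts* the final window with the
  package's own counter: the recorded truth is the realised count,
  accounting for GAGs inside planted GAGAs and background occurrences.
* Single-cell counts are negative binomial (common dispersion, default 0.5)
  with planted markers at a mean fold change in one cluster. No library-size
  variation, dropout structure, batch effects, or doublets.
* Hit tables give planted pairs dominant bitscores in both directions and
  arrange all other queries' best hits asymmetrically, enforced
  definitionally, so the reciprocal-best set equals the planted pairs.

Passing recovery tests on these data shows the *computations* are correct
under the stated conditions; it does not validate the biological pipeline
against real-data artifacts (mappability, peak-shape variation,
overdispersed backgrounds, annotation errors).

# Simulation sizes and numerical conventions

The test and acceptance simulations use: 20 true + 10 noise peaks per
replicate for recovery; ≤ 15 × 15 instances for exhaustive matching
checks; 10 000 random sequences for the counting oracle; marker power at
fold 8 with 100 cells per cluster over 100 replicates (200-gene matrices,
so the Bonferroni factor is realistic while each replicate stays fast); and
a 2 000-gene global null over 50 replicates, where the mean number of
flagged markers is required to stay below alpha × clusters — the bound
implied by Bonferroni's family-wise control. These sizes are the package's
choices for a self-contained desk-scale suite; all are parameters of the
generators and can be scaled up.

Degenerate inputs are defined, not errors: empty peak sets reconcile to
empty output; empty sequences count zero motifs; signals with no gene in
range produce explicit no-gene rows; a fraction with a zero denominator is
reported as 0. Rounding of displayed percentages is half-up. All
deterministic outputs (including run manifests, which contain no
timestamps) are byte-stable across reruns.

# Pipeline orchestration

`PipelineConfig` centralises the constants (q thresholds 0.005/0.001,
1-kb reconciliation, 10-kb window, ±150-bp flanks, 2-kb/10-kb upstream
windows, GAGA/GAG motifs, lKC clusters {1,2,6,7}, marker parameters) with
validity checks and exact YAML round-trips. `runPipeline` dispatches the
stages (`simulate`, `reconcile`, `targets`, `compare`, `motif-count`,
`rank`, `markers`, `intersect`, `rbh`, `report`) on files, writes outputs
atomically under fixed names, and records a JSON manifest of configuration,
input checksums and outputs. The `report` stage assembles summaries from
stage artifacts without recomputation. In R the functions are the primary
interface; `inst/scripts/run_pipeline.R` wraps them for shell use.

# Known limitations

* UTR labels require CDS records; annotations without CDS yield Exon/Intron
  labels only. BED12 CDS is recovered from the thick range only when it is
  a proper sub-range of the span.
* Whether published reconciliations measured summit, boundary, or midpoint
  distance — and whether upstream motif counts used one or both strands —
  are conventions the package exposes as options rather than facts it can
  settle.
* The marker test approximates the reference tools' behaviour (rank-sum on
  log-normalised expression, Bonferroni over all genes) but is not a
  reimplementation of any specific toolkit's normalisation; planted-truth
  power is demonstrated under the negative-binomial generator, not on real
  single-cell data.
* Fractions/percentages are reported at display precision (whole percent,
  half-up); downstream consumers needing exact ratios should use the id
  sets themselves.
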