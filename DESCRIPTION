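Package: gagaTargets
Title: Replicate-Reconciled ChIP-Seq Target Annotation and GAGA Motif
    Accumulation Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of transcription-factor ChIP-seq in the
    honey bee mushroom body and related hymenopteran comparative genomics.
    Reconciles peak calls from two biological replicates under a within-1-kb
    reproducibility rule, assigns reconciled binding signals to candidate
    target genes within a +/- 10 kb window with positional classification
    (UTR/exon/intron/upstream/downstream), compares condition-specific
    target sets, extracts peak-center windows for motif discovery input,
    counts GA-rich (GAGA/GAG) motifs in TSS-upstream windows with overlaps
    allowed, ranks genes by length-normalised expression, detects
    single-cell cluster markers by rank-sum testing, intersects markers
    with target catalogs, and resolves reciprocal-best-hit orthologs.
    Includes seeded synthetic-data generators with planted ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
biocViews: ChIPSeq, Annotation, MotifDiscovery, SingleCell, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'coordinates.R'
    'expression.R'
    'gagaTargets-package.R'
    'gene-annotation.R'
    'motifs.R'
    'narrowpeak-io.R'
    'pipeline.R'
    'reconcile.R'
    'simulate.R'
    'targets.R'
    'utils.R'
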