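Package: forksplice
Title: Replication Fork Restart and Intron Retention Analysis for
    Polymerase-Usage and Long-Read cDNA Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of replication fork restart and pre-mRNA splicing
    defects around a polar replication fork barrier in fission yeast.
    Computes per-strand polymerase usage and strand-combined polymerase
    bias tracks from binned polymerase-usage sequencing (Pu-seq) counts,
    detects the bias switch point at the barrier, and estimates the
    fraction of forks restarted by recombination-dependent replication.
    Quantifies per-intron retention from spliced long-read cDNA alignments
    (BED12), calls differential retention between conditions with a
    replicate-consistency filter, classifies transcripts against the
    reference intron chain, and profiles GC content around the 3' splice
    site with bootstrap confidence bands. Includes reversion-frequency
    statistics for the replication-slippage plating assay, and a synthetic
    data generator that produces toy genomes, 3'-anchored long reads,
    Pu-seq count tracks and plate counts so every stage runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Sequencing, Transcriptomics, AlternativeSplicing, Coverage,
    DNAReplication
RoxygenNote: 7.3.3
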