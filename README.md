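# forksplice

Replication fork restart and intron retention analysis for
polymerase-usage (Pu-seq) tracks and spliced long-read cDNA alignments.

## The problem

In fission yeast, a polar replication fork barrier (RFB) such as *RTS1*
arrests replication forks arriving from one direction; arrested forks
can restart by recombination-dependent replication (RDR), producing a
non-canonical fork in which Pol δ synthesizes **both** strands instead
of the canonical Pol ε (leading) / Pol δ (lagging) division. Loss of
barrier-associated factors also perturbs pre-mRNA splicing of a subset
of transcripts, raising intron retention. This package implements the
computations needed to study both phenomena, for people analysing
Pu-seq count tracks, Nanopore-style long-read cDNA alignments, and
slippage-assay plate counts — plus a synthetic-data layer so the whole
pipeline runs and is testable without any external data.

## The core quantities

**Polymerase bias.** From binned, strand-specific counts for a Pol δ
and a Pol ε mutant strain, per-strand Pol δ usage in bin *i* is
`u_δ,s,i = (n_δ,s,i + c) / (n_δ,s,i + n_ε,s,i + 2c)` on library-scaled
counts, and the strand-combined bias is
`bias_i = 100 · (u_δ,top,i + u_δ,bottom,i) / 2`. Canonical replication
gives 50 (whatever the fork direction); a fully restarted δ/δ fork
gives 100. The restarted-fork fraction over a window is
`f = (mean bias − 50) / 50`, clipped to [0, 1], with a bin-resampling
bootstrap SE.

**Intron retention.** Per intron and sample,
`IR = n_retained / (n_retained + n_spliced)`, where a read counts as
retained only if it covers >70% of the intron *and* of each flanking
exon (including the downstream exon), and as spliced only if a block
gap matches the intron junctions (±5 bp) with both exons covered.
Differential retention compares each mutant replicate with the pooled
wild type; a gene is called when some intron gains ≥20 percentage
points of retention in ≥2 replicates.

**Reversion frequency.** For the slippage assay,
`frequency = (mean selective count × selective dilution) /
(mean non-selective count × non-selective dilution)`, aggregated to
mean ± SD and compared by a two-tailed equal-variance Student's t test.

## Worked example

Restart-fraction estimation on simulated Pu-seq tracks with a 30%
arrest probability at the barrier:

```r
library(forksplice)
cfg    <- forkSimConfig(arrestProb = 0.3, seed = 1)
tracks <- simulatePuseqCounts(cfg)
bias   <- computeBias(computeUsage(tracks))
detectSwitchPoint(bias)
#> [1] 12001                      # the planted barrier is at 12001
est <- estimateRestartFraction(bias,
  c(cfg$barrierPos, cfg$barrierPos + 9000), seed = 1)
sprintf("f = %.3f +/- %.3f (n=%d bins)", est$f, est$f_se, est$n_bins)
#> [1] "f = 0.297 +/- 0.005 (n=30 bins)"
```

The estimated restarted-fork fraction (0.297 ± 0.005) recovers the
planted arrest probability 0.3; the switch point lands on the barrier
bin.

Differential intron retention with a planted retention increase
(intron 1 of gene `g002` retained at probability 0.5 in the mutant,
background 0.02, three replicates per condition):

```r
gm <- simulateGenome(nGenes = 6, seed = 1)
ov <- data.frame(gene_id = "g002", intron_index = 1,
                 condition = "MUT", prob = 0.5)
rc <- readSimConfig(depthPerGene = 300, retentionOverrides = ov, seed = 2)
reads <- do.call(c, c(
  lapply(1:3, function(r) simulateLongReads(gm, rc, "WT", r)),
  lapply(1:3, function(r) simulateLongReads(gm, rc, "MUT", r))))
d <- differentialRetention(quantifyRetention(reads, introns(gm)),
                           "WT", "MUT")
subset(d$table, gene_id == "g002")
#>  gene_id intron_index ir_wt_pooled delta_rep1 delta_rep2 delta_rep3
#>     g002            1        0.018       0.48       0.55       0.57
consistentRetentionGenes(d)
#> [1] "g002"
```

The wild-type baseline sits at the 0.02 background; every mutant
replicate gains ~0.5 retention and only the planted gene passes the
20%-in-2-of-3 consistency filter.

Slippage statistics from a plate-count table (a small synthetic
example ships with the package):

```r
p <- system.file("extdata", "slippage_counts_synthetic.tsv",
                 package = "forksplice")
rf <- reversionFrequency(SlippageExperiment(read.delim(p)))
rf$summary
#>          strain   condition mean_frequency sd_frequency n_experiments
#> 1 RTS1-ura4sd20 barrier_off       4.99e-05     1.44e-07             3
#> 2 RTS1-ura4sd20  barrier_on       2.59e-04     2.92e-05             3
```

An end-to-end demonstration (simulate → analyse → report) is

```sh
Rscript scripts/demo.R --out demo_out --seed 1
```

which writes every intermediate table plus `report.txt` comparing
planted and recovered parameters.

## Package layout

| Area | Functions |
| --- | --- |
| Core model | `Gene`, `GenomeModel`, `buildIntrons`, `introns`, `isoformSequence`, `compareIsoformProteins` |
| I/O | `readFasta`/`writeFasta`, `readGff3`/`writeGff3`, `readBed12`/`writeBed12`, `readBedgraph`/`writeBedgraph`, `readSampleManifest` |
| Simulation | `simulateGenome`, `simulateLongReads`, `simulatePuseqCounts`, `simulateSlippageCounts` (+ `*SimConfig` constructors) |
| Pu-seq | `PuseqTracks`, `computeUsage`, `computeBias`, `detectSwitchPoint`, `estimateRestartFraction`, `relativeRestart` |
| Retention | `callReadIntronStatus`, `quantifyRetention`, `differentialRetention`, `consistentRetentionGenes`, `classifyTranscripts`, `classProportions` |
| Sequence features | `gcProfile`, `gcNullBand`, `lengthVsDelta`, `expressionTable` |
| Slippage | `SlippageExperiment`, `reversionFrequency`, `compareFrequencies` |
| Demo | `runDemo`, `forkspliceConfig` |

See `vignettes/forksplice-methods.Rmd` for the models, parameter
defaults and their rationale, and known limitations.
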