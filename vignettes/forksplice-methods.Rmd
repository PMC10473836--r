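---
title: "Models and methods behind forksplice"
author: "forksplice authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind forksplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forksplice)
```

# Overview

forksplice analyses two linked phenomena around a polar replication fork
barrier (RFB) in fission yeast:

1. **Replication fork restart.** A fork arrested at the barrier can
   restart by recombination-dependent replication (RDR), producing a
   non-canonical fork in which Pol delta synthesizes *both* strands.
   Polymerase-usage sequencing (Pu-seq) maps ribonucleotides
   incorporated by mutant Pol delta and Pol epsilon strains, strand by
   strand, in genomic bins; from these four count tracks the package
   infers per-strand polymerase usage, the strand-combined *polymerase
   bias*, the position where the bias switches at the barrier, and the
   fraction of forks that restarted.
2. **Intron retention (IR).** Loss of the barrier-associated protein
   perturbs splicing of a subset of transcripts. From spliced long-read
   cDNA alignments the package counts, per intron and sample, reads
   that retain the intron versus reads that splice it, calls
   differential retention between conditions with a
   replicate-consistency filter, classifies whole reads against the
   reference intron chain, and profiles GC content around the 3' splice
   site (3'SS) where retention-prone introns show a GC dip.

A third, smaller component computes reversion frequencies for the
replication-slippage plating assay, and a synthetic-data layer
generates toy genomes, reads, tracks and plate counts with the
statistical structure the analyses assume, so that every stage runs and
is testable at desk scale.

# The polymerase-bias model

Let $n_{\delta,s,i}$ and $n_{\epsilon,s,i}$ be the library-scaled
counts for strand $s \in \{\text{top}, \text{bottom}\}$ in bin $i$.
Per-strand Pol delta usage is

$$u_{\delta,s,i} = \frac{n_{\delta,s,i} + c}{n_{\delta,s,i} +
n_{\epsilon,s,i} + 2c},$$

with pseudocount $c$ (default 0.5), and the strand-combined bias is

$$\mathrm{bias}_i = 100 \cdot
\tfrac{1}{2}(u_{\delta,\text{top},i} + u_{\delta,\text{bottom},i}).$$

A canonical fork uses Pol epsilon on the leading and Pol delta on the
lagging strand, so whichever direction the fork travels, one strand's
delta usage is ~1 and the other's ~0 and the bias is 50. A restarted
delta/delta fork pushes both usages toward 1 and the bias toward 100.
The restart fraction over a window is therefore
$f = (\overline{\mathrm{bias}} - 50)/50$, clipped to $[0, 1]$, with a
bin-resampling bootstrap SE.

**Library scaling.** When a `PuseqTracks` object carries
`libraryScale`, those per-strain factors are applied; otherwise the two
strains' totals over the analysed region are equalized. The simulator
emits `libraryScale = c(delta = 1, epsilon = 1)` because it generates
every track at the same per-fraction depth; region equalization would
otherwise be biased by the extra delta synthesis inside the restart
tract itself, which is visible at desk scale because the tract is a
large share of the simulated region (in genome-wide data the analysed
locus is a negligible share of the library and the distinction
vanishes).

**Defaults and why.** Pseudocount 0.5 and `minDepth` 20 per bin-strand
pair avoid 0/0 and unstable ratios in shallow bins; bins below
`minDepth` are reported missing rather than guessed. Bias smoothing is
a centered 3-bin moving average with truncated edges; smoothing is
cosmetic for display and is disabled (`smoothingWindow = 1`) wherever a
window mean is the quantity of interest, because averaging across the
tract boundary dilutes edge bins. The switch point is the leftmost run
of at least 3 bins at bias >= 60. The restart window defaults to
barrier to barrier + ~10 kb, the expected extent of the restarted
tract. Unbiasedness of $f$ is checked with `pseudocount = 0`: by the
Poisson splitting property the per-bin delta share is then exactly
binomial with mean equal to the planted fraction, so the estimator has
no shrinkage; the pseudocount trades a ~0.25% shrinkage toward 50 for
stability and is kept for real, noisy tracks.

# The fork-mixture simulator

Each bin is replicated by a rightward canonical fork (probability
$p_R$), a leftward canonical fork ($p_L$, the `leftwardFraction`), or a
rightward restarted fork ($p_{rr}$), with $p_R + p_L + p_{rr} = 1$.
Within the restart tract (barrier to barrier + `restartTractLen`,
default 9 kb ~ the observed ~10 kb), $p_{rr} = a(1 - p_L)$ where $a$
is the arrest probability; elsewhere $p_{rr} = 0$. Expected track
fractions follow from which polymerase makes which strand: delta/top
$= p_L + p_{rr}$, epsilon/top $= p_R$, delta/bottom $= p_R + p_{rr}$,
epsilon/bottom $= p_L$. Counts are Poisson with mean
`depth * fraction + background`. Closed form at $p_L = 0$: bias
$= 50 + 50a$, so $f$ recovers $a$ directly. Defaults (100 bins of 300
bp, depth 200 per bin per track, background 0, leftward fraction 0,
barrier at bin 41) are the desk-scale study conditions used throughout
the tests; Poisson rather than negative-binomial counts are the
simplest model consistent with the checks performed.

# Intron-retention calling

A read's status for an intron is decided feature-centrically:

* **RETAINED** — the read's aligned blocks cover more than 70% of the
  intron *and* of each flanking exon, including, explicitly, the exon
  downstream in transcription direction (a retention call requires the
  subsequent exonic sequence to be present, so a read that merely runs
  into an intron 3' end and stops is not counted).
* **SPLICED** — an inter-block gap coincides with the intron (both
  junctions within `junctionSlack`, default 5 bp of long-read wobble)
  and both flanking exons are covered above threshold.
* **NOT_COVERED** — the read does not touch the intron-plus-flanks
  region (or is on another chromosome).
* **AMBIGUOUS** — anything else, e.g. a 5'-degraded read ending inside
  the intron. Ambiguous and uncovered reads enter neither the retained
  nor the spliced count.

The ">70%" threshold is read as *feature-centric* (fraction of the
feature's bases covered by the read), strictly greater; a read-centric
reading would make the call depend on read length, which is dominated
by 5' degradation. Per-intron IR is $n_\text{ret}/(n_\text{ret} +
n_\text{spl})$, reported only when at least `minReads` (default 10)
informative reads support it, because low-coverage fractions are
unstable.

**Differential retention.** The wild-type baseline pools WT counts
across replicates (the comparison is mutant repeats against the
wild-type condition, with no stated pairing); each mutant replicate $r$
contributes $\Delta_r = \mathrm{IR}_{\text{mut},r} -
\mathrm{IR}_{\text{WT,pooled}}$. A Gaussian is fitted by moment
estimators to per-intron mean deltas, excluding exact zeros (introns
with no difference carry no signal about the shifted tail). A gene is
called *consistently retained* when any intron shows
$\Delta_r \ge 0.20$ — 20 percentage points, the natural reading of
"occurring 20% more often" — in at least 2 replicates. The call is an
effect-size-plus-replication filter by design; no p-values or multiple
testing correction are involved.

**Transcript classes.** Reads are classified against their gene's
intron chain with a deliberately minimal subset of the GffCompare
codes: `'='` (all introns inside the read span spliced by matching
gaps, no extra gaps — a *suffix* match, because 3'-anchored reads lose
5' exons), `'m'` (at least one intron retained, all gaps matching),
`'n'` (retention plus a novel gap), `'u'` (no gene overlap), `'other'`.
Full GffCompare parity is out of scope.

# The long-read simulator

Per gene, Poisson(`depthPerGene`) reads; each read retains each intron
independently with its retention probability (a base rate plus
per-intron, per-condition overrides); each read then loses an
exponential number of bases (mean `p5DegradationMean`, default 200 nt)
from the transcript 5' end, reflecting 5' degradation of polyA-selected
cDNA — the paper-level phenomenon is directional degradation of some
transcripts; the exponential is this package's modelling choice, as no
distribution is established. Reads are emitted as genomic blocks;
retained introns merge flanking blocks. The simulator reproduces
binomial sampling of retention exactly and is deterministic given its
seed; it does not model sequencing error, basecalling artefacts, or
replicate-to-replicate overdispersion beyond binomial (the true
overdispersion of IR fractions is unknown), so passing tests certify
the estimators under clean sampling noise, not robustness to alignment
artefacts.

# GC profile and bootstrap null band

For each intron the package takes the last 120 bases of the intron —
wide enough to span the typical yeast branch point at −10..−40 — and
the first 100 bases of the downstream exon, anchored at the 3'SS and
strand-aware. Per-position G+C indicators are smoothed within each
sequence (centered window, default 11 bp) and averaged over the group;
features shorter than the window contribute missing values, never
zeros. The null band draws `nSample` (default 100) introns uniformly
at random — the sampling scheme of the original 100-sequence interval
is not stated, and uniform sampling is the neutral choice — and
bootstraps the group-mean profile (default 1000 resamples), reporting
the percentile 2.5/97.5 band per position. A percentile rather than
normal-approximation interval is used because per-position GC means of
small samples are visibly non-Gaussian. Band coverage is verified on
binomial-GC synthetic sequences, and band width shrinks as roughly
$1/\sqrt{n}$.

The intron-length check uses Spearman rank correlation (lengths are
heavy-tailed); expression is compared as per-gene counts per million
mapped reads averaged within condition.

# Slippage statistics

Reversion frequency per experiment is the dilution-corrected ratio
$(\bar{n}_\text{sel} \cdot d_\text{sel}) / (\bar{n}_\text{nonsel}
\cdot d_\text{nonsel})$, where each $\bar{n}$ averages the two plates
of that medium. Experiments aggregate to mean ± SD; conditions are
compared by a classical equal-variance two-tailed Student's t test on
the raw frequency scale (the classical reading of "Student's t-test";
frequencies are not log-transformed, matching linear-scale
presentation). Zero pooled variance with unequal means is reported as
a degenerate comparison rather than an arbitrary finite t. Growth
duration is treated as metadata: the package reports frequencies, not
per-generation rates, and fluctuation (Luria–Delbrück) analysis is a
non-goal.

The plating simulator draws selective counts as Poisson with mean
`nCells/dilution * frequency` — the Poisson limit of the binomial
count of revertants among plated cells — and the estimator is checked
to be unbiased against it to within 5% relative error.

# Coordinates, conventions, degenerate inputs

* Internally everything is 1-based closed (the IRanges/GRanges
  convention); GFF3 (1-based closed) maps directly and BED12/bedGraph
  (0-based half-open) are converted at the I/O boundary.
* Intron indices follow transcription direction, so "intron 2" of a
  minus-strand gene is the second gap downstream of the transcription
  start, not the second gap in genomic order.
* Translation uses the standard nuclear code, stops at the first stop
  codon, and starts at the annotated CDS offset; the insertion-point
  comparison reports the length of the longest common protein prefix.
  The published insertion coordinates (15 residues between 202 and
  203) are reproduced on a constructed toy gene with the printed 45-bp
  intron geometry, since the real locus coordinates are not restated
  in this package.
* Single-exon genes have no introns (not an error); empty intron
  groups, windows without informative bins, all-zero strain libraries,
  and failed platings (zero viable counts) raise informative errors.
* All simulators accept a seed and restore the caller's RNG state.

# Problem sizes

The test and demonstration problem sizes are the package's chosen
desk-scale conditions: Pu-seq at 100 bins x 300 bp, depth 200 per bin
per track; retention experiments of 10-25 genes at 80-200 reads per
gene with 3 replicates per condition; GC-band calibration with 200
replications of 50-sequence samples and 200 bootstrap resamples; 1000
Monte-Carlo platings for the slippage estimator. The demonstration run
(`runDemo()`) uses 20 genes at depth 80 and writes every intermediate
table beside a plain-text report of planted versus recovered
parameters.

# Known limitations

* The Pu-seq normalization rule (library scale or region-equalized
  totals) is a documented default, not a claim about any published
  pipeline's internal normalization.
* IR calling consumes spliced alignments as BED12 blocks; alignment
  itself, basecalling, and CIGAR-level evidence are out of scope, as
  are novel splice-site discovery and isoform assembly.
* The gene-level consistency call inherits the pooled-WT baseline; a
  paired design would need a different delta definition.
* 5'-proximal introns lose informative reads under 5' degradation, so
  genome-wide retention counts are systematically conservative for
  long genes — the simulator reproduces this monotone coverage loss,
  and the tests assert it rather than correct for it.
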