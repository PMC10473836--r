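# Independent brute-force oracles. These deliberately avoid the package's
# interval arithmetic: everything is computed base by base or codon by
# codon so the fast implementations can be checked against them.

# Fraction of feature [fs, fe] covered by blocks (matrix with columns
# start, end), counting base by base.
oracleCoverage <- function(blocks, fs, fe) {
  covered <- 0L
  for (pos in fs:fe) {
    if (any(pos >= blocks[, 1L] & pos <= blocks[, 2L]))
      covered <- covered + 1L
  }
  covered / (fe - fs + 1L)
}

# Per-base re-implementation of the read/intron status rule.
# intron: list(start, end, up_start, up_end, down_start, down_end)
oracleStatus <- function(blocks, intron, thr = 0.70, slack = 5L) {
  region <- c(min(intron$start, intron$up_start, intron$down_start),
              max(intron$end, intron$up_end, intron$down_end))
  span <- c(min(blocks[, 1L]), max(blocks[, 2L]))
  if (span[2L] < region[1L] || span[1L] > region[2L])
    return("NOT_COVERED")
  covInt <- oracleCoverage(blocks, intron$start, intron$end)
  covUp <- oracleCoverage(blocks, intron$up_start, intron$up_end)
  covDown <- oracleCoverage(blocks, intron$down_start, intron$down_end)
  flanks <- covUp > thr && covDown > thr
  gap <- FALSE
  if (nrow(blocks) > 1L) {
    for (k in seq_len(nrow(blocks) - 1L)) {
      gs <- blocks[k, 2L] + 1L
      ge <- blocks[k + 1L, 1L] - 1L
      if (abs(gs - intron$start) <= slack && abs(ge - intron$end) <= slack)
        gap <- TRUE
    }
  }
  if (covInt > thr && flanks) return("RETAINED")
  if (gap && flanks) return("SPLICED")
  "AMBIGUOUS"
}

# Codon-table translation independent of Biostrings; stops at the first
# stop codon.
oracleTranslate <- function(dna) {
  codons <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
    CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
    TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
    GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
    AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
    CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  out <- character(0)
  for (i in seq(1L, nchar(dna) - 2L, by = 3L)) {
    aa <- codons[[substr(dna, i, i + 2L)]]
    if (aa == "*") break
    out <- c(out, aa)
  }
  paste(out, collapse = "")
}

oracleRevComp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
}

# Draw nCases random read/intron pairs on the toy three-exon locus and
# return the fast caller's statuses alongside the per-base oracle's.
statusAgreement <- function(nCases, seed) {
  g <- Gene("gX", "chrI", "+",
    IRanges::IRanges(c(101, 301, 501), c(200, 400, 600)))
  ig <- buildIntrons(g)
  set.seed(seed)
  got <- character(0); want <- character(0)
  while (length(got) < nCases) {
    intron <- ig[sample(2, 1)]
    if (runif(1) < 0.3) {
      # junction-proximal case: a gap near the intron with +/- 7 bp jitter
      is_ <- GenomicRanges::start(intron); ie <- GenomicRanges::end(intron)
      bm <- matrix(c(sample(50:(is_ - 30L), 1L), is_ - 1L + sample(-7:7, 1L),
        ie + 1L + sample(-7:7, 1L), sample((ie + 30L):650L, 1L)),
        ncol = 2L, byrow = TRUE)
      if (bm[1L, 1L] >= bm[1L, 2L] || bm[2L, 1L] >= bm[2L, 2L] ||
          bm[2L, 1L] <= bm[1L, 2L] + 1L) next
    } else {
      nb <- sample(1:3, 1L)
      cuts <- sort(sample(50:650, 2L * nb))
      bm <- matrix(cuts, ncol = 2L, byrow = TRUE)
      if (nb > 1L && any(bm[-1L, 1L] <= bm[-nb, 2L] + 1L)) next
    }
    r <- makeReads(list(bm))
    m <- S4Vectors::mcols(intron)
    got <- c(got, callReadIntronStatus(r[[1]], intron))
    want <- c(want, oracleStatus(bm, list(
      start = GenomicRanges::start(intron),
      end = GenomicRanges::end(intron),
      up_start = m$up_start, up_end = m$up_end,
      down_start = m$down_start, down_end = m$down_end)))
  }
  list(got = got, want = want)
}

# GC fraction of a string, counted character by character.
oracleGC <- function(s) {
  ch <- strsplit(s, "")[[1L]]
  mean(ch %in% c("G", "C"))
}
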