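# Fixtures built in code: tiny hand-checkable genomes and gene models.

# Plus-strand two-exon toy: exons 1..3 ("AAA") and 13..15 ("CCC"),
# intron 4..12 ("GTATGTAAG" backbone, i.e. gt..ag boundaries).
toyTwoExonGenome <- function() {
  #          123 456789012 345
  chrSeq <- "AAAGTATGAAAGCCC"
  g <- Gene("toy", "chrI", "+", IRanges::IRanges(c(1, 13), c(3, 15)))
  GenomeModel(c(chrI = chrSeq), list(g))
}

# A random multi-exon toy gene on a random chromosome background;
# returns the GenomeModel and the per-piece sense-strand sequences so
# expected transcripts can be assembled by hand.
randomToyGenome <- function(nExons = 3L, strand = "+", seed = 1L,
    exonLen = c(6L, 12L), intronLen = c(5L, 9L)) {
  set.seed(seed)
  nIntrons <- nExons - 1L
  exSeq <- vapply(seq_len(nExons), function(i)
    paste(sample(c("A", "C", "G", "T"),
      sample(seq(exonLen[1L], exonLen[2L]), 1L), replace = TRUE),
      collapse = ""), character(1))
  inSeq <- vapply(seq_len(max(nIntrons, 0L)), function(i) {
    n <- sample(seq(intronLen[1L], intronLen[2L]), 1L)
    mid <- paste(sample(c("A", "C", "G", "T"), n - 4L, replace = TRUE),
      collapse = "")
    paste0("GT", mid, "AG")
  }, character(1))
  sense <- character(0)
  for (i in seq_len(nExons)) {
    sense <- c(sense, exSeq[i])
    if (i <= nIntrons) sense <- c(sense, inSeq[i])
  }
  senseSeq <- paste(sense, collapse = "")
  L <- nchar(senseSeq)
  pieceLen <- nchar(sense)
  senseStart <- cumsum(c(1L, pieceLen[-length(pieceLen)]))
  senseEnd <- senseStart + pieceLen - 1L
  exIdx <- seq(1L, length(sense), by = 2L)
  if (strand == "+") {
    chrSeq <- senseSeq
    exStart <- senseStart[exIdx]; exEnd <- senseEnd[exIdx]
  } else {
    chrSeq <- oracleRevComp(senseSeq)
    exStart <- L - senseEnd[exIdx] + 1L
    exEnd <- L - senseStart[exIdx] + 1L
  }
  g <- Gene("rtoy", "chrI", strand, IRanges::IRanges(exStart, exEnd))
  list(genome = GenomeModel(c(chrI = chrSeq), list(g)),
    exSeq = exSeq, inSeq = inSeq)
}

# Toy gene with a 45-bp stop-free second intron placed exactly between
# codons 202 and 203 of the CDS: the construction used to check the
# in-frame 15-residue insertion.
toyInsertionGenome <- function(intron2Len = 45L) {
  stopifnot(intron2Len >= 7L)
  utr <- "AAAA"                     # 4 nt 5' UTR in exon 1
  # exon 1: UTR + start codon + 9 codons; intron 1 in the 5' part of CDS
  ex1Cds <- paste(rep("GAA", 10L), collapse = "")   # M replaced below
  ex1Cds <- paste0("ATG", substr(ex1Cds, 4L, nchar(ex1Cds)))
  intron1 <- "GTCCAAATTAG"
  # exon 2: codons 11..202 (192 codons of GAT = D)
  ex2 <- paste(rep("GAT", 192L), collapse = "")
  # intron 2: in-frame stop-free codons bracketed by GT..AG
  nMid <- (intron2Len - 6L) / 3L
  intron2 <- if (intron2Len %% 3L == 0L)
    paste0("GTA", paste(rep("GCT", nMid), collapse = ""), "CAG")
  else # non-multiple-of-3 variant: pad with extra bases before AG
    paste0("GTA", paste(rep("GCT", (intron2Len - 6L) %/% 3L),
      collapse = ""), substr("TTTT", 1L, (intron2Len - 6L) %% 3L), "CAG")
  # exon 3: codons 203.. (30 codons of AAA = K) + stop
  ex3 <- paste0(paste(rep("AAA", 30L), collapse = ""), "TAA", "GGGG")
  chrSeq <- paste0(utr, ex1Cds, intron1, ex2, intron2, ex3)
  b1 <- nchar(utr) + nchar(ex1Cds)
  b2 <- b1 + nchar(intron1)
  b3 <- b2 + nchar(ex2)
  b4 <- b3 + nchar(intron2)
  g <- Gene("toyins", "chrI", "+",
    IRanges::IRanges(c(1L, b2 + 1L, b4 + 1L),
      c(b1, b3, b4 + nchar(ex3))),
    cdsStartOffset = nchar(utr))
  GenomeModel(c(chrI = chrSeq), list(g))
}

# Genome holding the three-exon classification locus (exons 101..200,
# 301..400, 501..600 on the plus strand) on a 1-kb chromosome.
toyClassGenome <- function() {
  g <- Gene("gX", "chrI", "+",
    IRanges::IRanges(c(101, 301, 501), c(200, 400, 600)))
  GenomeModel(c(chrI = paste(rep("A", 1000), collapse = "")), list(g))
}

# A GRangesList of reads from plain block coordinates.
makeReads <- function(blockList, chrom = "chrI", sampleId = "s1",
    condition = "WT", replicate = 1L) {
  u <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(
      unlist(lapply(blockList, function(b) b[, 1L])),
      unlist(lapply(blockList, function(b) b[, 2L]))))
  reads <- S4Vectors::split(u,
    rep(seq_along(blockList), vapply(blockList, nrow, integer(1))))
  names(reads) <- NULL
  S4Vectors::mcols(reads) <- S4Vectors::DataFrame(
    read_id = sprintf("%s_r%03d", sampleId, seq_along(blockList)),
    sample_id = sampleId, condition = condition,
    replicate = as.integer(replicate))
  reads
}

blockMat <- function(...) {
  v <- c(...)
  matrix(v, ncol = 2L, byrow = TRUE)
}
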