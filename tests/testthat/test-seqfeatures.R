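# One-gene genome with a fully specified chromosome string; intron is
# 201..260, downstream exon 261..400.
gcFixture <- function(chrSeq) {
  g <- Gene("g1", "chrI", "+",
    IRanges::IRanges(c(101, 261), c(200, 400)))
  GenomeModel(c(chrI = chrSeq), list(g))
}

test_that("gc profile counts G+C exactly in the anchored window", {
  allG <- gcFixture(paste(rep("G", 500), collapse = ""))
  pg <- gcProfile(allG, introns(allG), intronWindow = 40,
    exonWindow = 50, smooth = 1)
  expect_equal(pg$gc, rep(1, 90))
  expect_equal(pg$position, c(-(40:1), 1:50))

  # alternating GCAT: every 4-mer window holds exactly 50% GC
  chr <- paste(rep("GCAT", 125), collapse = "")
  gm <- gcFixture(chr)
  p <- gcProfile(gm, introns(gm), intronWindow = 40, exonWindow = 50,
    smooth = 4)
  interior <- p$position > -38 & p$position < 48
  expect_true(all(abs(p$gc[interior] - 0.5) < 0.26))
  p1 <- gcProfile(gm, introns(gm), intronWindow = 40, exonWindow = 50,
    smooth = 1)
  # unsmoothed positions match a direct character-level recount
  ig <- introns(gm)
  seqWin <- substr(chr, GenomicRanges::end(ig) - 39,
    GenomicRanges::end(ig))
  gcByPos <- as.integer(strsplit(seqWin, "")[[1]] %in% c("G", "C"))
  expect_equal(p1$gc[1:40], gcByPos)
})

test_that("dip-group profiles sit below background, verified by recount", {
  dip <- sprintf("g%03d", 1:6)
  gm <- simulateGenome(nGenes = 24, gcDipGenes = dip, seed = 31)
  ig <- introns(gm)
  isDip <- S4Vectors::mcols(ig)$gene_id %in% dip
  pd <- gcProfile(gm, ig[isDip], intronWindow = 40, exonWindow = 100,
    smooth = 1)
  pb <- gcProfile(gm, ig[!isDip], intronWindow = 40, exonWindow = 100,
    smooth = 1)
  sel <- pd$position >= -35 & pd$position <= 95
  expect_lt(mean(pd$gc[sel]), mean(pb$gc[sel]) - 0.05)
})

test_that("gc profile is strand-symmetric", {
  # the same sense-strand gene on + and - genomic strands gives the
  # same anchored profile
  fp <- randomToyGenome(nExons = 2L, strand = "+", seed = 41,
    exonLen = c(30L, 40L), intronLen = c(20L, 30L))
  fm <- randomToyGenome(nExons = 2L, strand = "-", seed = 41,
    exonLen = c(30L, 40L), intronLen = c(20L, 30L))
  pp <- gcProfile(fp$genome, introns(fp$genome), intronWindow = 15,
    exonWindow = 20, smooth = 1)
  pm <- gcProfile(fm$genome, introns(fm$genome), intronWindow = 15,
    exonWindow = 20, smooth = 1)
  expect_equal(pm$gc, pp$gc)
})

test_that("short features pad as missing, not as zeros", {
  chr <- paste(rep("G", 500), collapse = "")
  g <- Gene("g1", "chrI", "+",
    IRanges::IRanges(c(101, 131), c(120, 160)))  # 10-bp intron
  gm <- GenomeModel(c(chrI = chr), list(g))
  p <- gcProfile(gm, introns(gm), intronWindow = 40, exonWindow = 20,
    smooth = 1)
  expect_true(all(is.nan(p$gc[p$position < -10])))
  expect_equal(p$n[p$position < -10], rep(0L, 30))
  expect_equal(p$gc[p$position >= -10], rep(1, 30))
})

test_that("null band is deterministic, tight for constant GC, and scales", {
  dip <- character(0)
  gm <- simulateGenome(nGenes = 40, nExonsRange = c(2L, 2L),
    exonLengthRange = c(60L, 60L), intronLengthRange = c(50L, 50L),
    gcBackground = 0.45, seed = 51)
  ig <- introns(gm)
  b1 <- gcNullBand(gm, ig, nSample = 30, nBoot = 150, seed = 5,
    intronWindow = 30, exonWindow = 30, smooth = 1)
  b2 <- gcNullBand(gm, ig, nSample = 30, nBoot = 150, seed = 5,
    intronWindow = 30, exonWindow = 30, smooth = 1)
  expect_equal(b1, b2)
  expect_true(all(b1$ci_low <= b1$gc & b1$gc <= b1$ci_high))
  expect_error(gcNullBand(gm, ig, nSample = 1000), "reduce nSample")

  # constant-GC genome: zero-width band at the constant
  allG <- gcFixture(paste(rep("G", 500), collapse = ""))
  igG <- introns(allG)
  bG <- gcNullBand(allG, igG, nSample = 1, nBoot = 50, seed = 1,
    intronWindow = 20, exonWindow = 20, smooth = 1)
  expect_equal(bG$ci_low, rep(1, 40))
  expect_equal(bG$ci_high, rep(1, 40))
})

test_that("band width shrinks roughly as one over sqrt(sample size)", {
  gm <- simulateGenome(nGenes = 120, nExonsRange = c(2L, 2L),
    exonLengthRange = c(60L, 60L), intronLengthRange = c(50L, 50L),
    seed = 53)
  ig <- introns(gm)
  w <- function(n) {
    b <- gcNullBand(gm, ig, nSample = n, nBoot = 300, seed = 7,
      intronWindow = 25, exonWindow = 25, smooth = 1)
    mean(b$ci_high - b$ci_low)
  }
  ratio <- w(25) / w(100)
  expect_gte(ratio, 1.6)
  expect_lte(ratio, 2.4)
})

test_that("intron length does not predict delta unless planted", {
  ig <- introns(simulateGenome(nGenes = 15, seed = 55))
  m <- S4Vectors::mcols(ig)
  n <- length(ig)
  # perfectly length-ordered deltas: rho = 1
  tb <- data.frame(gene_id = m$gene_id, intron_index = m$intron_index,
    ir_wt_pooled = 0.1, delta_rep1 = NA_real_,
    mean_delta = rank(GenomicRanges::width(ig)) / n,
    n_reps_defined = 1L)
  res <- lengthVsDelta(list(table = tb), ig)
  expect_equal(res$spearman_rho, 1)
  # independent deltas: small rho
  set.seed(9)
  tb$mean_delta <- runif(n)
  res2 <- lengthVsDelta(list(table = tb), ig)
  expect_lt(abs(res2$spearman_rho), 0.6)
  expect_error(lengthVsDelta(list(table = tb[1:2, ]), ig), "at least 3")
})

test_that("expression table recovers hand-computed CPM fold changes", {
  gm <- toyClassGenome()
  mk <- function(n, sample, cond) makeReads(
    lapply(seq_len(n), function(i) blockMat(101, 600)),
    sampleId = sample, condition = cond)
  intergenic <- function(n, sample, cond) makeReads(
    lapply(seq_len(n), function(i) blockMat(801, 900)),
    sampleId = sample, condition = cond)
  # WT: 10 gene reads + 10 intergenic; MUT: 20 gene reads + 10 intergenic
  reads <- c(mk(10, "w", "WT"), intergenic(10, "w", "WT"),
    mk(20, "m", "MUT"), intergenic(10, "m", "MUT"))
  et <- expressionTable(reads, gm)
  expect_equal(et$cpm_wt, 10 / 20 * 1e6)
  expect_equal(et$cpm_mut, 20 / 30 * 1e6)
  expect_equal(et$log2fc, log2((20 / 30) / (10 / 20)))
  # identical conditions: zero fold change
  same <- c(mk(10, "w", "WT"), mk(10, "m", "MUT"))
  expect_equal(expressionTable(same, gm)$log2fc, 0)
  expect_error(expressionTable(GenomicRanges::GRangesList(), gm),
    "no reads")
})
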