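test_that("simulated genomes are deterministic with canonical introns", {
  gm1 <- simulateGenome(nGenes = 5, seed = 7)
  gm2 <- simulateGenome(nGenes = 5, seed = 7)
  expect_equal(as.character(chromosomes(gm1)[[1]]),
    as.character(chromosomes(gm2)[[1]]))
  expect_true(validObject(gm1))
  ig <- introns(gm1)
  chr <- chromosomes(gm1)[[1]]
  for (i in seq_along(ig)) {
    s <- as.character(Biostrings::subseq(chr,
      GenomicRanges::start(ig)[i], GenomicRanges::end(ig)[i]))
    if (as.character(GenomicRanges::strand(ig))[i] == "-")
      s <- oracleRevComp(s)
    expect_equal(substr(s, 1, 2), "GT")
    expect_equal(substr(s, nchar(s) - 1, nchar(s)), "AG")
  }
})

test_that("GC-dip genes have lower GC in the 3'SS window than background", {
  dip <- sprintf("g%03d", 1:5)
  gm <- simulateGenome(nGenes = 20, gcDipGenes = dip, seed = 3)
  ig <- introns(gm)
  isDip <- S4Vectors::mcols(ig)$gene_id %in% dip
  # direct unsmoothed recount with the character-level oracle
  windowGC <- function(i) {
    chr <- as.character(chromosomes(gm)[[1]])
    str <- as.character(GenomicRanges::strand(ig))[i]
    m <- S4Vectors::mcols(ig)[i, ]
    if (str == "+") {
      s <- substr(chr, GenomicRanges::end(ig)[i] - 39,
        min(m$down_start + 99, m$down_end))
    } else {
      s <- substr(chr, max(m$down_start, m$down_end - 99),
        GenomicRanges::start(ig)[i] + 39)
    }
    oracleGC(s)
  }
  gcDipMean <- mean(vapply(which(isDip), windowGC, numeric(1)))
  gcBgMean <- mean(vapply(which(!isDip), windowGC, numeric(1)))
  expect_lt(gcDipMean, gcBgMean - 0.05)
})

test_that("reads splice or retain exactly as the probabilities dictate", {
  gm <- simulateGenome(nGenes = 4, seed = 2)
  ig <- introns(gm)
  # retention 0: every read gap coincides with an annotated intron
  cfg0 <- readSimConfig(depthPerGene = 30, baseRetention = 0,
    p5DegradationMean = 0, seed = 5)
  rd0 <- simulateLongReads(gm, cfg0, "WT", 1)
  intronKey <- paste(GenomicRanges::start(ig), GenomicRanges::end(ig))
  for (i in seq_along(rd0)) {
    b <- rd0[[i]]
    if (length(b) < 2) next
    gs <- GenomicRanges::end(b)[-length(b)] + 1L
    ge <- GenomicRanges::start(b)[-1L] - 1L
    expect_true(all(paste(gs, ge) %in% intronKey))
  }
  # retention 1 for every intron: no read has any gap
  cfg1 <- readSimConfig(depthPerGene = 30, baseRetention = 1,
    p5DegradationMean = 0, seed = 5)
  rd1 <- simulateLongReads(gm, cfg1, "WT", 1)
  expect_true(all(lengths(rd1) == 1L))
  # determinism
  rd0b <- simulateLongReads(gm, cfg0, "WT", 1)
  expect_identical(S4Vectors::mcols(rd0)$read_id,
    S4Vectors::mcols(rd0b)$read_id)
  expect_equal(unname(lengths(rd0)), unname(lengths(rd0b)))
})

test_that("empirical retention matches the planted probability", {
  gm <- simulateGenome(nGenes = 1, nExonsRange = c(3L, 3L), seed = 4)
  cfg <- readSimConfig(depthPerGene = 200, baseRetention = 0.3,
    p5DegradationMean = 0, seed = 9)
  rd <- simulateLongReads(gm, cfg, "WT", 1)
  ig <- introns(gm)
  tb <- quantifyRetention(rd, ig, minReads = 10)
  for (i in seq_len(nrow(tb))) {
    ci <- binom.test(tb$n_retained[i],
      tb$n_retained[i] + tb$n_spliced[i])$conf.int
    expect_gte(0.3, ci[1])
    expect_lte(0.3, ci[2])
  }
})

test_that("5' degradation reduces informative coverage of 5' introns", {
  gm <- simulateGenome(nGenes = 6, nExonsRange = c(4L, 4L), seed = 11)
  ig <- introns(gm)
  first <- ig[S4Vectors::mcols(ig)$intron_index == 1L]
  inform <- function(p5) {
    cfg <- readSimConfig(depthPerGene = 60, baseRetention = 0.1,
      p5DegradationMean = p5, seed = 13)
    tb <- quantifyRetention(
      simulateLongReads(gm, cfg, "WT", 1, seed = 13), first, minReads = 1)
    sum(tb$n_retained + tb$n_spliced)
  }
  n0 <- inform(0)
  n400 <- inform(400)
  n1200 <- inform(1200)
  expect_lt(n400, n0)
  expect_lt(n1200, n400)
})

test_that("Pu-seq fork mixture obeys the generative algebra", {
  # a = 0, no leftward forks: delta top strand empty, epsilon top full
  c0 <- forkSimConfig(arrestProb = 0, depth = 200, seed = 21)
  t0 <- simulatePuseqCounts(c0)
  cnt0 <- SummarizedExperiment::assay(t0)
  expect_equal(sum(cnt0[, "delta_top"]), 0)
  expect_equal(mean(cnt0[, "epsilon_top"]), 200, tolerance = 0.05)
  expect_equal(mean(cnt0[, "delta_bottom"]), 200, tolerance = 0.05)
  # a = 1: downstream tract is delta/delta on both strands
  c1 <- forkSimConfig(arrestProb = 1, depth = 200, seed = 21)
  t1 <- simulatePuseqCounts(c1)
  cnt1 <- SummarizedExperiment::assay(t1)
  mid <- GenomicRanges::start(SummarizedExperiment::rowRanges(t1)) + 150
  tract <- mid > c1$barrierPos & mid <= c1$barrierPos + c1$restartTractLen
  expect_equal(sum(cnt1[tract, "epsilon_top"]), 0)
  expect_equal(sum(cnt1[tract, "epsilon_bottom"]), 0)
  expect_equal(mean(cnt1[tract, "delta_top"]), 200, tolerance = 0.05)
  # a = 0.5: delta and epsilon split the top strand evenly downstream
  ch <- forkSimConfig(arrestProb = 0.5, depth = 200, seed = 21)
  th <- simulatePuseqCounts(ch)
  cnth <- SummarizedExperiment::assay(th)
  r <- sum(cnth[tract, "delta_top"]) /
    (sum(cnth[tract, "delta_top"]) + sum(cnth[tract, "epsilon_top"]))
  expect_equal(r, 0.5, tolerance = 0.04)
  # determinism
  expect_equal(SummarizedExperiment::assay(simulatePuseqCounts(c1)), cnt1)
})

test_that("slippage counts follow the plating model", {
  cfg0 <- slippageSimConfig(trueSlipFreq = 0, seed = 31)
  s0 <- simulateSlippageCounts(cfg0)
  expect_true(all(plateCounts(s0)$selective1 == 0))
  expect_true(all(plateCounts(s0)$selective2 == 0))
  cfg <- slippageSimConfig(trueSlipFreq = 5e-4, seed = 32)
  expect_equal(plateCounts(simulateSlippageCounts(cfg)),
    plateCounts(simulateSlippageCounts(cfg)))
})
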