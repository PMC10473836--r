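# A shared toy locus: gene with exons 101..200, 301..400, 501..600
# (introns 201..300 and 401..500), plus strand.
retGene <- function() Gene("gX", "chrI",
  "+", IRanges::IRanges(c(101, 301, 501), c(200, 400, 600)))
retIntrons <- function() buildIntrons(retGene())

test_that("per-read intron status follows the coverage and junction rules", {
  ig <- retIntrons()
  i1 <- ig[1]
  # full coverage of intron 1 and both flanking exons: RETAINED
  r <- makeReads(list(blockMat(101, 420)))
  expect_equal(callReadIntronStatus(r[[1]], i1), "RETAINED")
  # clean junction gap with both exons covered: SPLICED
  r <- makeReads(list(blockMat(101, 200, 301, 400)))
  expect_equal(callReadIntronStatus(r[[1]], i1), "SPLICED")
  # junction within slack still SPLICED
  r <- makeReads(list(blockMat(101, 203, 298, 400)))
  expect_equal(callReadIntronStatus(r[[1]], i1, junctionSlack = 5),
    "SPLICED")
  expect_equal(callReadIntronStatus(r[[1]], i1, junctionSlack = 2),
    "AMBIGUOUS")
  # 5'-degraded read covering only 60% of the intron: AMBIGUOUS
  r <- makeReads(list(blockMat(241, 420)))
  expect_equal(callReadIntronStatus(r[[1]], i1), "AMBIGUOUS")
  # read elsewhere on the chromosome / other chromosome: NOT_COVERED
  r <- makeReads(list(blockMat(701, 800)))
  expect_equal(callReadIntronStatus(r[[1]], i1), "NOT_COVERED")
  r <- makeReads(list(blockMat(101, 420)), chrom = "chrII")
  expect_equal(callReadIntronStatus(r[[1]], i1), "NOT_COVERED")
  # retained call requires the downstream exon too: read stopping at the
  # intron 3' junction is not retained
  r <- makeReads(list(blockMat(101, 300)))
  expect_equal(callReadIntronStatus(r[[1]], i1), "AMBIGUOUS")
})

test_that("status calls agree with a per-base brute-force oracle", {
  res <- statusAgreement(200, seed = 404)
  expect_equal(res$got, res$want)
  # all four statuses exercised by the random cases
  expect_setequal(unique(res$want),
    c("RETAINED", "SPLICED", "AMBIGUOUS", "NOT_COVERED"))
})

test_that("retention quantification counts informative reads per sample", {
  ig <- retIntrons()
  spliced <- lapply(1:10, function(i) blockMat(101, 200, 301, 400))
  reads <- makeReads(spliced)
  tb <- quantifyRetention(reads, ig[1], minReads = 10)
  expect_equal(tb$n_retained, 0L)
  expect_equal(tb$n_spliced, 10L)
  expect_equal(tb$ir_fraction, 0)

  mixed <- makeReads(c(
    lapply(1:5, function(i) blockMat(101, 420)),
    lapply(1:5, function(i) blockMat(101, 200, 301, 400))))
  tb2 <- quantifyRetention(mixed, ig[1], minReads = 10)
  expect_equal(tb2$ir_fraction, 0.5)
  # below min_reads the fraction is reported missing, counts kept
  tb3 <- quantifyRetention(mixed, ig[1], minReads = 11)
  expect_equal(tb3$n_retained, 5L)
  expect_true(is.na(tb3$ir_fraction))
})

test_that("retention counts are order-invariant and shard-additive", {
  gm <- simulateGenome(nGenes = 4, seed = 6)
  ig <- introns(gm)
  cfg <- readSimConfig(depthPerGene = 40, baseRetention = 0.2, seed = 8)
  rd <- simulateLongReads(gm, cfg, "WT", 1)
  tb <- quantifyRetention(rd, ig, minReads = 1)
  perm <- sample(length(rd))
  tbp <- quantifyRetention(rd[perm], ig, minReads = 1)
  key <- order(tb$gene_id, tb$intron_index)
  keyp <- order(tbp$gene_id, tbp$intron_index)
  expect_equal(tb$n_retained[key], tbp$n_retained[keyp])
  expect_equal(tb$n_spliced[key], tbp$n_spliced[keyp])
  # sharding: counts add across disjoint read subsets
  half <- seq_len(floor(length(rd) / 2))
  t1 <- quantifyRetention(rd[half], ig, minReads = 1)
  t2 <- quantifyRetention(rd[-half], ig, minReads = 1)
  expect_equal(t1$n_retained[order(t1$gene_id, t1$intron_index)] +
    t2$n_retained[order(t2$gene_id, t2$intron_index)],
    tb$n_retained[key])
})

test_that("differential retention uses pooled WT and fits nonzero deltas", {
  ig <- retIntrons()[1]
  mk <- function(nRet, nTot, sample, cond, rep_) {
    blocks <- c(
      lapply(seq_len(nRet), function(i) blockMat(101, 420)),
      lapply(seq_len(nTot - nRet), function(i)
        blockMat(101, 200, 301, 400)))
    makeReads(blocks, sampleId = sample, condition = cond,
      replicate = rep_)
  }
  reads <- c(mk(2, 20, "wt1", "WT", 1), mk(4, 20, "wt2", "WT", 2),
    mk(10, 20, "m1", "MUT", 1), mk(16, 20, "m2", "MUT", 2))
  tb <- quantifyRetention(reads, ig, minReads = 10)
  d <- differentialRetention(tb, "WT", "MUT")
  # pooled WT: 6/40 = 0.15; deltas 0.5-0.15 and 0.8-0.15
  expect_equal(d$table$ir_wt_pooled, 0.15)
  expect_equal(d$table$delta_rep1, 0.35)
  expect_equal(d$table$delta_rep2, 0.65)
  expect_equal(d$table$mean_delta, 0.5)

  # identical conditions: all deltas zero, excluded from the fit
  same <- c(mk(5, 20, "wt1", "WT", 1), mk(5, 20, "m1", "MUT", 1),
    mk(5, 20, "m2", "MUT", 2))
  d0 <- differentialRetention(quantifyRetention(same, ig, minReads = 10),
    "WT", "MUT")
  expect_equal(d0$table$mean_delta, 0)
  expect_equal(d0$fit$n, 0L)
})

test_that("the moment fit matches the closed form on fixed deltas", {
  # three introns with WT IR 0.2 and MUT IR 0.1 / 0.2 / 0.3:
  # deltas {-0.1, 0, +0.1}; the zero delta is excluded from the fit
  tb <- rbind(
    data.frame(gene_id = c("a", "b", "c"), intron_index = 1L,
      chrom = "chrI", start = 1L, end = 10L, sample_id = "wt1",
      condition = "WT", replicate = 1L, n_retained = 4L,
      n_spliced = 16L, ir_fraction = 0.2),
    data.frame(gene_id = c("a", "b", "c"), intron_index = 1L,
      chrom = "chrI", start = 1L, end = 10L, sample_id = "m1",
      condition = "MUT", replicate = 1L,
      n_retained = c(2L, 4L, 6L), n_spliced = c(18L, 16L, 14L),
      ir_fraction = c(0.1, 0.2, 0.3)))
  d <- differentialRetention(tb, "WT", "MUT")
  expect_equal(sort(d$table$delta_rep1), c(-0.1, 0, 0.1))
  expect_equal(d$fit$n, 2L)
  expect_equal(d$fit$mu, 0)
  expect_equal(d$fit$sigma, 0.1)  # population moment over {-0.1, 0.1}
})

test_that("the consistency filter applies the delta/replicate rule", {
  mkdiff <- function(deltas) list(table = data.frame(
    gene_id = "gA", intron_index = 1L, ir_wt_pooled = 0.1,
    delta_rep1 = deltas[1], delta_rep2 = deltas[2],
    delta_rep3 = deltas[3],
    mean_delta = mean(deltas), n_reps_defined = 3L))
  expect_equal(consistentRetentionGenes(mkdiff(c(0.25, 0.22, 0.05))),
    "gA")
  expect_equal(consistentRetentionGenes(mkdiff(c(0.25, 0.10, 0.10))),
    character(0))
  # exactly at threshold counts ("20% more often" inclusive)
  expect_equal(consistentRetentionGenes(mkdiff(c(0.20, 0.20, 0))), "gA")
})

test_that("planted differential retention is recovered gene by gene", {
  gm <- simulateGenome(nGenes = 8, nExonsRange = c(3L, 3L), seed = 23)
  ig <- introns(gm)
  planted <- data.frame(gene_id = c("g002", "g005"), intron_index = 1L,
    condition = "MUT", prob = 0.5)
  cfg <- readSimConfig(depthPerGene = 80, baseRetention = 0.02,
    retentionOverrides = planted, p5DegradationMean = 100, seed = 27)
  reads <- do.call(c, c(
    lapply(1:3, function(r) simulateLongReads(gm, cfg, "WT", r)),
    lapply(1:3, function(r) simulateLongReads(gm, cfg, "MUT", r))))
  tb <- quantifyRetention(reads, ig)
  d <- differentialRetention(tb, "WT", "MUT")
  called <- consistentRetentionGenes(d)
  expect_true(all(c("g002", "g005") %in% called))
  expect_lte(length(setdiff(called, c("g002", "g005"))), 1L)
})

test_that("transcript classes follow the intron-chain comparison", {
  gm <- toyClassGenome()
  reads <- makeReads(list(
    blockMat(101, 200, 301, 400, 501, 600),  # fully spliced: '='
    blockMat(350, 400, 501, 600),            # 5'-truncated spliced: '='
    blockMat(101, 400, 501, 600),            # intron 1 retained: 'm'
    blockMat(101, 600),                      # both introns retained: 'm'
    blockMat(101, 400, 501, 530, 561, 600),  # retention + novel gap: 'n'
    blockMat(801, 900),                      # intergenic: 'u'
    blockMat(101, 200, 301, 340)             # ends inside intron 2: '='
  ))
  cl <- classifyTranscripts(reads, gm)
  expect_equal(cl$code, c("=", "=", "m", "m", "n", "u", "="))
  expect_equal(cl$gene_id[6], NA_character_)

  pr <- classProportions(cl)
  expect_equal(sum(pr$fraction), 1)
  expect_equal(pr$fraction[pr$code == "m"], 2 / 7)
})
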