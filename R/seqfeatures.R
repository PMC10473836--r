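# GC-richness profiling around the 3' splice site, bootstrap null bands,
# and the intron-length / expression sanity checks.
#
# Offsets are relative to the 3' splice site in transcription direction:
# -intronWindow .. -1 lie inside the intron (the window is long enough to
# span the typical yeast branch point at -10..-40), +1 .. +exonWindow lie
# in the downstream exon.

# Per-intron GC indicator rows over the profiling window; NA where the
# feature is shorter than the window (padded as missing, not zeros).
.gcMatrix <- function(genome, intronsGR, intronWindow, exonWindow) {
  if (!length(intronsGR)) stop("empty intron group")
  n <- length(intronsGR)
  ncolTot <- intronWindow + exonWindow
  mat <- matrix(NA_real_, nrow = n, ncol = ncolTot)
  chroms <- chromosomes(genome)
  m <- mcols(intronsGR)
  for (i in seq_len(n)) {
    chr <- chroms[[as.character(seqnames(intronsGR))[i]]]
    str <- as.character(strand(intronsGR))[i]
    iw <- min(intronWindow, width(intronsGR)[i])
    dw <- min(exonWindow, m$down_end[i] - m$down_start[i] + 1L)
    if (str == "+") {
      intronPart <- subseq(chr, end(intronsGR)[i] - iw + 1L,
        end(intronsGR)[i])
      exonPart <- subseq(chr, m$down_start[i], m$down_start[i] + dw - 1L)
      s <- paste0(as.character(intronPart), as.character(exonPart))
    } else {
      intronPart <- subseq(chr, start(intronsGR)[i],
        start(intronsGR)[i] + iw - 1L)
      exonPart <- subseq(chr, m$down_end[i] - dw + 1L, m$down_end[i])
      s <- as.character(reverseComplement(
        Biostrings::xscat(exonPart, intronPart)))
    }
    gc <- as.integer(strsplit(s, "")[[1L]] %in% c("G", "C"))
    mat[i, (intronWindow - iw + 1L):(intronWindow + dw)] <- gc
  }
  colnames(mat) <- as.character(c(-(intronWindow:1), seq_len(exonWindow)))
  mat
}

.smoothRows <- function(mat, smooth) {
  if (smooth <= 1L) return(mat)
  sm <- t(apply(mat, 1L, movingAverage, window = smooth))
  dimnames(sm) <- dimnames(mat)
  sm
}

#' GC profile of a group of introns around the 3' splice site
#'
#' For each intron, takes the last \code{intronWindow} bases of the
#' intron (covering the branch-point region) and the first
#' \code{exonWindow} bases of the downstream exon in transcription
#' direction, computes a per-position GC indicator, smooths each
#' sequence with a centered sliding window, and averages across the
#' group. Features shorter than the window contribute missing values,
#' not zeros.
#'
#' @param genome a [GenomeModel-class].
#' @param intronsGR intron group (rows of [introns()] output).
#' @param intronWindow,exonWindow window extents (bp) on either side of
#'   the 3' splice site.
#' @param smooth sliding-window width (bp); 1 disables smoothing.
#' @return A data.frame with \code{position} (negative = intronic,
#'   positive = downstream exon), \code{gc} (mean GC fraction) and
#'   \code{n} (sequences contributing at that position).
#' @export
gcProfile <- function(genome, intronsGR, intronWindow = 120L,
    exonWindow = 100L, smooth = 11L) {
  mat <- .smoothRows(
    .gcMatrix(genome, intronsGR, intronWindow, exonWindow), smooth)
  data.frame(
    position = as.integer(colnames(mat)),
    gc = colMeans(mat, na.rm = TRUE),
    n = colSums(!is.na(mat)),
    row.names = NULL)
}

#' Bootstrap null band for the group-mean GC profile
#'
#' Draws \code{nSample} introns at random, then bootstraps the
#' group-mean profile \code{nBoot} times (resampling sequences with
#' replacement) and reports the per-position percentile band. A group
#' profile falling outside this band departs from what a random sample
#' of introns of the same size would show.
#'
#' @param genome a [GenomeModel-class].
#' @param allIntrons the population of introns to sample from.
#' @param nSample sample size (error if fewer introns are available).
#' @param level confidence level for the percentile band.
#' @param nBoot bootstrap replicates.
#' @param seed RNG seed.
#' @param intronWindow,exonWindow,smooth as in [gcProfile()].
#' @return A data.frame with \code{position}, \code{gc} (sample mean),
#'   \code{ci_low}, \code{ci_high}.
#' @export
gcNullBand <- function(genome, allIntrons, nSample = 100L, level = 0.95,
    nBoot = 1000L, seed = 1L, intronWindow = 120L, exonWindow = 100L,
    smooth = 11L) {
  if (length(allIntrons) < nSample)
    stop("only ", length(allIntrons), " introns available; reduce nSample")
  withSeed(seed, {
    pick <- sample(length(allIntrons), nSample)
    mat <- .smoothRows(
      .gcMatrix(genome, allIntrons[pick], intronWindow, exonWindow),
      smooth)
    boots <- matrix(NA_real_, nrow = nBoot, ncol = ncol(mat))
    for (b in seq_len(nBoot)) {
      rows <- sample.int(nSample, replace = TRUE)
      boots[b, ] <- colMeans(mat[rows, , drop = FALSE], na.rm = TRUE)
    }
    alpha <- (1 - level) / 2
    data.frame(
      position = as.integer(colnames(mat)),
      gc = colMeans(mat, na.rm = TRUE),
      ci_low = apply(boots, 2L, quantile, probs = alpha, na.rm = TRUE),
      ci_high = apply(boots, 2L, quantile, probs = 1 - alpha,
        na.rm = TRUE),
      row.names = NULL)
  })
}

#' Correlation between intron length and retention change
#'
#' Spearman rank correlation of intron length against the per-intron
#' mean retention change (mutant minus wild type).
#'
#' @param diff output of [differentialRetention()].
#' @param intronsGR introns matching the differential table.
#' @return A list with \code{spearman_rho}, \code{p} and \code{n}.
#' @export
lengthVsDelta <- function(diff, intronsGR) {
  tb <- diff$table
  key <- paste(mcols(intronsGR)$gene_id, mcols(intronsGR)$intron_index,
    sep = "|")
  len <- width(intronsGR)[match(paste(tb$gene_id, tb$intron_index,
    sep = "|"), key)]
  ok <- !is.na(len) & !is.na(tb$mean_delta)
  if (sum(ok) < 3L)
    stop("need at least 3 introns with defined length and delta")
  ct <- suppressWarnings(cor.test(len[ok], tb$mean_delta[ok],
    method = "spearman", exact = FALSE))
  list(spearman_rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Per-gene expression comparison between conditions
#'
#' Assigns each read to the gene it overlaps most, scales per-sample
#' gene counts to counts per million mapped reads, averages CPM within
#' condition, and reports per-gene log2 fold changes (mutant over wild
#' type).
#'
#' @param reads a [GenomicRanges::GRangesList] with sample metadata.
#' @param genome a [GenomeModel-class].
#' @param wtCondition,mutCondition condition labels.
#' @return A data.frame with \code{gene_id}, \code{cpm_wt},
#'   \code{cpm_mut}, \code{log2fc}.
#' @export
expressionTable <- function(reads, genome, wtCondition = "WT",
    mutCondition = "MUT") {
  if (!length(reads)) stop("no reads supplied")
  spans <- readSpans(reads)
  gr <- geneRanges(genome)
  hits <- findOverlaps(spans, gr, ignore.strand = TRUE)
  ovw <- pmin(end(spans)[queryHits(hits)], end(gr)[subjectHits(hits)]) -
    pmax(start(spans)[queryHits(hits)], start(gr)[subjectHits(hits)]) + 1L
  o <- order(queryHits(hits), -ovw)
  keep <- !duplicated(queryHits(hits)[o])
  readGene <- rep(NA_integer_, length(reads))
  readGene[queryHits(hits)[o][keep]] <- subjectHits(hits)[o][keep]

  meta <- mcols(reads)
  samples <- unique(data.frame(sample_id = meta$sample_id,
    condition = meta$condition, stringsAsFactors = FALSE))
  if (any(!samples$condition %in% c(wtCondition, mutCondition)))
    samples <- samples[samples$condition %in%
      c(wtCondition, mutCondition), , drop = FALSE]
  ids <- gr$gene_id
  cpm <- matrix(0, nrow = length(ids), ncol = nrow(samples),
    dimnames = list(ids, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    sel <- meta$sample_id == samples$sample_id[j]
    tot <- sum(sel)
    if (tot == 0L) stop("sample ", samples$sample_id[j], " has no reads")
    cnt <- table(factor(readGene[sel], levels = seq_along(ids)))
    cpm[, j] <- as.numeric(cnt) / tot * 1e6
  }
  cpmWt <- rowMeans(cpm[, samples$condition == wtCondition, drop = FALSE])
  cpmMut <- rowMeans(cpm[, samples$condition == mutCondition,
    drop = FALSE])
  data.frame(gene_id = ids, cpm_wt = cpmWt, cpm_mut = cpmMut,
    log2fc = log2(cpmMut / cpmWt), row.names = NULL,
    stringsAsFactors = FALSE)
}
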