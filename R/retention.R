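# Intron-retention calling from spliced long-read alignments.
#
# A read is RETAINED for an intron when its aligned blocks cover more
# than `overlapThreshold` of the intron AND of each flanking exon
# (including, explicitly, the downstream exon in transcription
# direction); SPLICED when an inter-block gap coincides with the intron
# (both junctions within `junctionSlack`) and both flanking exons are
# covered; NOT_COVERED when the read does not touch the
# intron-plus-flanks region; AMBIGUOUS otherwise (e.g. a 5'-degraded
# read ending inside the intron).

.STATUS <- c("RETAINED", "SPLICED", "AMBIGUOUS", "NOT_COVERED")

# Vectorized status engine over (readIdx, intronIdx) pairs.
.callStatusPairs <- function(flat, intronsGR, readIdx, intronIdx,
    overlapThreshold, junctionSlack) {
  is_ <- start(intronsGR)[intronIdx]
  ie <- end(intronsGR)[intronIdx]
  m <- mcols(intronsGR)
  us <- m$up_start[intronIdx]; ue <- m$up_end[intronIdx]
  ds <- m$down_start[intronIdx]; de <- m$down_end[intronIdx]
  covInt <- coveredBases(flat, readIdx, is_, ie) / (ie - is_ + 1)
  covUp <- coveredBases(flat, readIdx, us, ue) / (ue - us + 1)
  covDown <- coveredBases(flat, readIdx, ds, de) / (de - ds + 1)
  gap <- hasMatchingGap(flat, readIdx, is_, ie, junctionSlack)
  flanksOk <- covUp > overlapThreshold & covDown > overlapThreshold
  status <- rep.int("AMBIGUOUS", length(readIdx))
  status[gap & flanksOk] <- "SPLICED"
  status[covInt > overlapThreshold & flanksOk] <- "RETAINED"
  status
}

# Region an intron call can see: intron plus both flanking exons.
.intronFlankRegion <- function(intronsGR) {
  m <- mcols(intronsGR)
  GRanges(seqnames(intronsGR),
    IRanges(pmin(start(intronsGR), m$up_start, m$down_start),
            pmax(end(intronsGR), m$up_end, m$down_end)))
}

#' Call one read's status for one intron
#'
#' @param read a single-element [GenomicRanges::GRangesList] (or a
#'   [GenomicRanges::GRanges] of one read's blocks).
#' @param intron a single-row intron [GenomicRanges::GRanges] as produced
#'   by [buildIntrons()].
#' @param overlapThreshold minimum covered fraction of the intron and of
#'   each flanking exon (strictly greater than) for a RETAINED call.
#' @param junctionSlack maximum distance (bp) between a read gap junction
#'   and the annotated intron boundary for a SPLICED call.
#' @return One of \code{"RETAINED"}, \code{"SPLICED"},
#'   \code{"AMBIGUOUS"}, \code{"NOT_COVERED"}. A chromosome mismatch
#'   yields \code{"NOT_COVERED"}.
#' @export
callReadIntronStatus <- function(read, intron, overlapThreshold = 0.70,
    junctionSlack = 5L) {
  if (is(read, "GRanges")) read <- GRangesList(read)
  stopifnot(length(read) == 1L, length(intron) == 1L)
  if (as.character(seqnames(read[[1L]]))[1L] !=
      as.character(seqnames(intron)))
    return("NOT_COVERED")
  region <- .intronFlankRegion(intron)
  sp <- range(read[[1L]])
  if (end(sp) < start(region) || start(sp) > end(region))
    return("NOT_COVERED")
  flat <- flattenBlocks(read)
  .callStatusPairs(flat, intron, 1L, 1L, overlapThreshold, junctionSlack)
}

# All (read, intron) status calls for reads overlapping each intron's
# flank region. Returns a data.frame of pairs with status.
.callAll <- function(reads, intronsGR, overlapThreshold, junctionSlack) {
  if (!length(reads) || !length(intronsGR))
    return(data.frame(readIdx = integer(0), intronIdx = integer(0),
      status = character(0)))
  spans <- readSpans(reads)
  region <- .intronFlankRegion(intronsGR)
  hits <- findOverlaps(spans, region, ignore.strand = TRUE)
  readIdx <- queryHits(hits); intronIdx <- subjectHits(hits)
  flat <- flattenBlocks(reads)
  status <- .callStatusPairs(flat, intronsGR, readIdx, intronIdx,
    overlapThreshold, junctionSlack)
  data.frame(readIdx = readIdx, intronIdx = intronIdx, status = status)
}

#' Quantify per-intron retention per sample
#'
#' For every intron and sample, counts reads called RETAINED and SPLICED
#' (AMBIGUOUS and NOT_COVERED reads enter neither count) and reports the
#' intron-retention fraction \code{n_retained / (n_retained + n_spliced)},
#' missing where fewer than \code{minReads} informative reads support the
#' intron.
#'
#' @param reads a [GenomicRanges::GRangesList] with sample metadata, as
#'   from [readBed12()], [readSampleManifest()] or [simulateLongReads()].
#' @param intronsGR introns from [buildIntrons()]/[introns()].
#' @param minReads minimum informative reads for a reported fraction.
#' @param overlapThreshold,junctionSlack see [callReadIntronStatus()].
#' @return A data.frame with one row per (intron, sample):
#'   \code{gene_id}, \code{intron_index}, \code{chrom}, \code{start},
#'   \code{end} (1-based closed), \code{sample_id}, \code{condition},
#'   \code{replicate}, \code{n_retained}, \code{n_spliced},
#'   \code{ir_fraction}.
#' @export
quantifyRetention <- function(reads, intronsGR, minReads = 10L,
    overlapThreshold = 0.70, junctionSlack = 5L) {
  calls <- .callAll(reads, intronsGR, overlapThreshold, junctionSlack)
  meta <- mcols(reads)
  samples <- unique(data.frame(
    sample_id = meta$sample_id, condition = meta$condition,
    replicate = meta$replicate, stringsAsFactors = FALSE))
  calls <- calls[calls$status %in% c("RETAINED", "SPLICED"), , drop = FALSE]
  calls$sample_id <- meta$sample_id[calls$readIdx]
  key <- interaction(calls$intronIdx, calls$sample_id, drop = FALSE)
  grid <- expand.grid(intronIdx = seq_along(intronsGR),
    sample_id = samples$sample_id, stringsAsFactors = FALSE)
  tab <- function(st) {
    sub <- calls[calls$status == st, , drop = FALSE]
    if (!nrow(sub)) return(integer(nrow(grid)))
    agg <- table(factor(sub$intronIdx, levels = seq_along(intronsGR)),
      factor(sub$sample_id, levels = samples$sample_id))
    as.integer(agg[cbind(grid$intronIdx,
      match(grid$sample_id, samples$sample_id))])
  }
  nRet <- tab("RETAINED"); nSpl <- tab("SPLICED")
  tot <- nRet + nSpl
  irf <- ifelse(tot >= minReads & tot > 0, nRet / tot, NA_real_)
  m <- mcols(intronsGR)
  si <- match(grid$sample_id, samples$sample_id)
  data.frame(
    gene_id = m$gene_id[grid$intronIdx],
    intron_index = m$intron_index[grid$intronIdx],
    chrom = as.character(seqnames(intronsGR))[grid$intronIdx],
    start = start(intronsGR)[grid$intronIdx],
    end = end(intronsGR)[grid$intronIdx],
    sample_id = grid$sample_id,
    condition = samples$condition[si],
    replicate = samples$replicate[si],
    n_retained = nRet, n_spliced = nSpl, ir_fraction = irf,
    stringsAsFactors = FALSE)
}

#' Differential intron retention between two conditions
#'
#' For each intron, the wild-type baseline is the IR fraction of the
#' pooled WT counts (all WT replicates summed); each mutant replicate
#' contributes \code{delta_r = IR_mut,r - IR_wt_pooled}. A Gaussian is
#' fitted by moment estimators to the per-intron mean deltas, excluding
#' introns whose mean delta is exactly zero (no difference between
#' conditions).
#'
#' @param table output of [quantifyRetention()].
#' @param wtCondition,mutCondition condition labels.
#' @param minReads minimum pooled/replicate informative reads for a
#'   defined fraction.
#' @return A list with \code{table} (one row per intron: \code{gene_id},
#'   \code{intron_index}, \code{ir_wt_pooled}, \code{delta_rep<k>}
#'   columns, \code{mean_delta}, \code{n_reps_defined}) and \code{fit}
#'   (list \code{mu}, \code{sigma}, \code{n}).
#' @export
differentialRetention <- function(table, wtCondition = "WT",
    mutCondition = "MUT", minReads = 10L) {
  wt <- table[table$condition == wtCondition, , drop = FALSE]
  mut <- table[table$condition == mutCondition, , drop = FALSE]
  if (!nrow(wt) || !nrow(mut))
    stop("need rows for both conditions '", wtCondition, "' and '",
      mutCondition, "'")
  ikey <- function(df) paste(df$gene_id, df$intron_index, sep = "|")
  wtAgg <- aggregate(cbind(n_retained, n_spliced) ~ gene_id + intron_index,
    data = wt, FUN = sum)
  wtTot <- wtAgg$n_retained + wtAgg$n_spliced
  wtAgg$ir_wt_pooled <- ifelse(wtTot >= minReads & wtTot > 0,
    wtAgg$n_retained / wtTot, NA_real_)
  reps <- sort(unique(mut$replicate))
  out <- wtAgg[, c("gene_id", "intron_index", "ir_wt_pooled")]
  okey <- ikey(out)
  for (r in reps) {
    mr <- mut[mut$replicate == r, , drop = FALSE]
    d <- mr$ir_fraction[match(okey, ikey(mr))] - out$ir_wt_pooled
    out[[sprintf("delta_rep%d", r)]] <- d
  }
  dcols <- grep("^delta_rep", names(out))
  dmat <- as.matrix(out[, dcols, drop = FALSE])
  out$mean_delta <- rowMeans(dmat, na.rm = TRUE)
  out$mean_delta[!is.finite(out$mean_delta)] <- NA_real_
  out$n_reps_defined <- rowSums(!is.na(dmat))
  nz <- out$mean_delta[!is.na(out$mean_delta) & out$mean_delta != 0]
  fit <- if (length(nz) >= 2L)
    list(mu = mean(nz), sigma = sd(nz) * sqrt((length(nz) - 1) / length(nz)),
      n = length(nz))
  else list(mu = NA_real_, sigma = NA_real_, n = length(nz))
  list(table = out, fit = fit)
}

#' Genes with replicate-consistent increased retention
#'
#' A gene is called when any of its introns shows a retention increase of
#' at least \code{minDelta} (fraction units; 20 percentage points by
#' default) in at least \code{minReps} mutant replicates relative to the
#' pooled wild type.
#'
#' @param diff output of [differentialRetention()].
#' @param minDelta minimum per-replicate IR increase (fraction units).
#' @param minReps minimum number of replicates meeting \code{minDelta}.
#' @return Character vector of gene ids, sorted.
#' @export
consistentRetentionGenes <- function(diff, minDelta = 0.20, minReps = 2L) {
  tb <- diff$table
  dmat <- as.matrix(tb[, grep("^delta_rep", names(tb)), drop = FALSE])
  nOver <- rowSums(dmat >= minDelta, na.rm = TRUE)
  sort(unique(tb$gene_id[nOver >= minReps]))
}

#' Classify reads against the reference intron chain
#'
#' Minimal transcript classification in the style of GffCompare codes:
#' \code{'='} — every intron inside the read span is spliced out by a
#' matching gap and there are no extra gaps (a suffix match tolerates 5'
#' truncation of 3'-anchored reads); \code{'m'} — at least one reference
#' intron is retained and every observed gap matches a reference intron;
#' \code{'n'} — retention plus at least one non-matching gap;
#' \code{'u'} — the read overlaps no gene; \code{'other'} — anything
#' else. An intron counts as retained when both its junctions lie inside
#' the read span, no gap matches it, and the read's blocks cover more
#' than \code{overlapThreshold} of it.
#'
#' @param reads a [GenomicRanges::GRangesList] of reads.
#' @param genome a [GenomeModel-class].
#' @param junctionSlack junction matching tolerance (bp).
#' @param overlapThreshold coverage fraction qualifying a retained intron.
#' @return A data.frame with \code{read_id}, \code{sample_id},
#'   \code{gene_id} (NA for \code{'u'}) and \code{code}.
#' @export
classifyTranscripts <- function(reads, genome, junctionSlack = 5L,
    overlapThreshold = 0.70) {
  spans <- readSpans(reads)
  gr <- geneRanges(genome)
  hits <- findOverlaps(spans, gr, ignore.strand = TRUE)
  # most-overlap wins
  ovw <- pmin(end(spans)[queryHits(hits)], end(gr)[subjectHits(hits)]) -
    pmax(start(spans)[queryHits(hits)], start(gr)[subjectHits(hits)]) + 1L
  o <- order(queryHits(hits), -ovw)
  keep <- !duplicated(queryHits(hits)[o])
  assign_ <- rep(NA_integer_, length(reads))
  assign_[queryHits(hits)[o][keep]] <- subjectHits(hits)[o][keep]

  flat <- flattenBlocks(reads)
  allIntrons <- lapply(genes(genome), buildIntrons)
  codes <- rep.int("u", length(reads))
  for (i in seq_along(reads)) {
    gi <- assign_[i]
    if (is.na(gi)) next
    gid <- gr$gene_id[gi]
    ig <- allIntrons[[gid]]
    sp <- c(start(spans)[i], end(spans)[i])
    ng <- flat$nGaps[i]
    gapS <- if (ng) flat$gapStart[seq.int(flat$gapFirst[i],
      length.out = ng)] else integer(0)
    gapE <- if (ng) flat$gapEnd[seq.int(flat$gapFirst[i],
      length.out = ng)] else integer(0)
    inside <- which(start(ig) >= sp[1L] & end(ig) <= sp[2L])
    matched <- logical(length(inside))
    gapMatched <- logical(ng)
    for (k in seq_along(inside)) {
      j <- inside[k]
      hit <- which(abs(gapS - start(ig)[j]) <= junctionSlack &
                   abs(gapE - end(ig)[j]) <= junctionSlack)
      if (length(hit)) {
        matched[k] <- TRUE
        gapMatched[hit] <- TRUE
      }
    }
    extraGaps <- ng - sum(gapMatched)
    retained <- 0L
    for (k in seq_along(inside)) {
      if (matched[k]) next
      j <- inside[k]
      cov <- coveredBases(flat, i, start(ig)[j], end(ig)[j]) /
        width(ig)[j]
      if (cov > overlapThreshold) retained <- retained + 1L
    }
    unaccounted <- sum(!matched) - retained
    codes[i] <-
      if (retained > 0L && extraGaps == 0L && unaccounted == 0L) "m"
      else if (retained > 0L && extraGaps > 0L) "n"
      else if (retained == 0L && extraGaps == 0L && unaccounted == 0L) "="
      else "other"
  }
  data.frame(read_id = mcols(reads)$read_id,
    sample_id = mcols(reads)$sample_id,
    gene_id = ifelse(is.na(assign_), NA_character_,
      gr$gene_id[assign_]),
    code = codes, stringsAsFactors = FALSE)
}

#' Per-sample transcript class proportions
#'
#' @param classes output of [classifyTranscripts()].
#' @return A data.frame with \code{sample_id}, \code{code},
#'   \code{fraction}; fractions sum to 1 within each sample.
#' @export
classProportions <- function(classes) {
  tab <- table(classes$sample_id, classes$code)
  prop <- prop.table(tab, margin = 1)
  df <- as.data.frame(prop, stringsAsFactors = FALSE)
  names(df) <- c("sample_id", "code", "fraction")
  df[order(df$sample_id, df$code), , drop = FALSE]
}
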