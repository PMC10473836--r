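# Polymerase usage, strand-combined bias, barrier switch point, and
# restart-fraction estimation from 4-track Pu-seq counts.
#
# Per strand, Pol-delta usage in a bin is the ratio of the delta-strain
# count to the sum of delta- and epsilon-strain counts after library
# scaling. The strand-combined "polymerase bias" is
# 100 * (usage_delta_top + usage_delta_bottom) / 2: canonical
# epsilon/delta replication gives 50 regardless of fork direction, while
# a fully restarted delta/delta fork gives 100.

#' Compute per-strand Pol-delta usage from Pu-seq counts
#'
#' Counts are first put on a common library scale: if the track set
#' carries \code{libraryScale}, those per-strain factors are applied;
#' otherwise the two strains' totals (both strands) over the analysed
#' region are equalized. Per bin and strand,
#' \code{usage_delta = (n_delta + pc) / (n_delta + n_epsilon + 2 pc)}
#' on the scaled counts; Pol-epsilon usage is its complement. Bins whose
#' raw (unscaled) strand total is below \code{minDepth} are flagged
#' missing.
#'
#' @param tracks a [PuseqTracks-class].
#' @param minDepth minimum raw count (delta + epsilon) per bin-strand
#'   pair below which usage is reported as \code{NA}.
#' @param pseudocount added to each strain's scaled count.
#' @return A [GenomicRanges::GRanges] of the bins with metadata columns
#'   \code{usage_delta_top}, \code{usage_delta_bottom} in [0, 1]
#'   (\code{NA} = insufficient depth).
#' @export
computeUsage <- function(tracks, minDepth = 20L, pseudocount = 0.5) {
  stopifnot(is(tracks, "PuseqTracks"))
  cnt <- assay(tracks, "counts")
  totDelta <- sum(cnt[, c("delta_top", "delta_bottom")])
  totEps <- sum(cnt[, c("epsilon_top", "epsilon_bottom")])
  if (totDelta == 0 || totEps == 0)
    stop("unusable library: a strain's counts are all zero")
  ls <- metadata(tracks)$libraryScale
  if (is.null(ls)) {
    target <- (totDelta + totEps) / 2
    ls <- c(delta = target / totDelta, epsilon = target / totEps)
  }
  sc <- cnt
  sc[, c("delta_top", "delta_bottom")] <-
    sc[, c("delta_top", "delta_bottom")] * ls[["delta"]]
  sc[, c("epsilon_top", "epsilon_bottom")] <-
    sc[, c("epsilon_top", "epsilon_bottom")] * ls[["epsilon"]]
  pc <- pseudocount
  uTop <- (sc[, "delta_top"] + pc) /
    (sc[, "delta_top"] + sc[, "epsilon_top"] + 2 * pc)
  uBot <- (sc[, "delta_bottom"] + pc) /
    (sc[, "delta_bottom"] + sc[, "epsilon_bottom"] + 2 * pc)
  uTop[cnt[, "delta_top"] + cnt[, "epsilon_top"] < minDepth] <- NA_real_
  uBot[cnt[, "delta_bottom"] + cnt[, "epsilon_bottom"] < minDepth] <-
    NA_real_
  out <- granges(rowRanges(tracks))
  mcols(out) <- DataFrame(usage_delta_top = as.numeric(uTop),
    usage_delta_bottom = as.numeric(uBot))
  out
}

#' Strand-combined polymerase-bias track
#'
#' \code{bias_pct = 100 * (usage_delta_top + usage_delta_bottom) / 2},
#' smoothed with a centered moving average (edges truncated). Canonical
#' replication gives 50, a pure delta/delta restarted fork 100; missing
#' usage bins stay missing.
#'
#' @param usage output of [computeUsage()].
#' @param smoothingWindow moving-average width in bins.
#' @return A [GenomicRanges::GRanges] with metadata column
#'   \code{bias_pct} in [0, 100] and metadata entry
#'   \code{smoothingWindow}.
#' @export
computeBias <- function(usage, smoothingWindow = 3L) {
  stopifnot(all(c("usage_delta_top", "usage_delta_bottom") %in%
    names(mcols(usage))))
  raw <- 100 * (usage$usage_delta_top + usage$usage_delta_bottom) / 2
  out <- granges(usage)
  mcols(out) <- DataFrame(bias_pct = movingAverage(raw, smoothingWindow))
  metadata(out)$smoothingWindow <- as.integer(smoothingWindow)
  out
}

#' Detect the bias switch point at the barrier
#'
#' The leftmost bin start at which \code{bias_pct} stays at or above
#' \code{thresholdPct} for at least \code{minRunBins} consecutive bins —
#' the abrupt switch to Pol-delta usage expected where restarted forks
#' take over.
#'
#' @param bias output of [computeBias()].
#' @param thresholdPct bias threshold (percent).
#' @param minRunBins minimum run length in bins.
#' @return The genomic start coordinate of the switch bin, or \code{NA}
#'   if no qualifying run exists.
#' @export
detectSwitchPoint <- function(bias, thresholdPct = 60, minRunBins = 3L) {
  hi <- !is.na(bias$bias_pct) & bias$bias_pct >= thresholdPct
  r <- rle(hi)
  runEnd <- cumsum(r$lengths)
  runStart <- runEnd - r$lengths + 1L
  ok <- which(r$values & r$lengths >= minRunBins)
  if (!length(ok)) return(NA_integer_)
  start(bias)[runStart[ok[1L]]]
}

#' Estimate the restarted-fork fraction over a window
#'
#' \code{f = (mean bias over the window - 50) / 50}, clipped to [0, 1]:
#' the proportion of forks through the window that are restarted
#' delta/delta forks rather than canonical. The standard error is a
#' bin-resampling bootstrap.
#'
#' @param bias output of [computeBias()].
#' @param window a [GenomicRanges::GRanges] (or \code{c(start, end)}
#'   numeric on the bias track's chromosome) delimiting the restart
#'   tract, typically barrier to barrier + ~10 kb.
#' @param nBoot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return A list with \code{f}, \code{f_se} and \code{n_bins}.
#' @export
estimateRestartFraction <- function(bias, window, nBoot = 1000L,
    seed = NULL) {
  if (is.numeric(window) && length(window) == 2L)
    window <- GRanges(as.character(seqnames(bias))[1L],
      IRanges(window[1L], window[2L]))
  # a bin belongs to the window iff its midpoint does: insensitive to
  # bins straddling the window edges
  mid <- (start(bias) + end(bias)) / 2
  hit <- which(as.character(seqnames(bias)) ==
      as.character(seqnames(window))[1L] &
    mid >= start(window)[1L] & mid <= end(window)[1L])
  b <- bias$bias_pct[hit]
  b <- b[!is.na(b)]
  if (!length(b))
    stop("no bias bins with defined values inside the window")
  f <- clip01((mean(b) - 50) / 50)
  fSE <- withSeed(seed, {
    boots <- vapply(seq_len(nBoot), function(i)
      clip01((mean(sample(b, replace = TRUE)) - 50) / 50), numeric(1))
    sd(boots)
  })
  list(f = f, f_se = fSE, n_bins = length(b))
}

#' Restart fraction of a mutant relative to wild type
#'
#' @param fMut,fWt restart fractions (scalars or the lists returned by
#'   [estimateRestartFraction()]).
#' @return \code{fMut / fWt}.
#' @export
relativeRestart <- function(fMut, fWt) {
  if (is.list(fMut)) fMut <- fMut$f
  if (is.list(fWt)) fWt <- fWt$f
  if (fWt <= 0)
    stop("wild-type restart fraction is zero; relative restart undefined")
  fMut / fWt
}
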