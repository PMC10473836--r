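# Internal numerical helpers.

# Evaluate expr with a locally-set RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Centered moving average with truncated edges; NA inputs stay NA in the
# output but are dropped from neighbouring windows.
movingAverage <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L || length(x) < 2L) return(x)
  half <- window %/% 2L
  n <- length(x)
  out <- vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
  out[is.na(x)] <- NA_real_
  out
}

# Flat representation of per-read blocks and inter-block gaps: blocks of
# a GRangesList unlist grouped by read, so per-read rows are contiguous.
flattenBlocks <- function(reads) {
  u <- unlist(reads, use.names = FALSE)
  n <- lengths(reads)
  firstRow <- c(0L, cumsum(n))[seq_along(n)] + 1L
  bs <- start(u); be <- end(u)
  # gaps between consecutive blocks of the same read
  ng <- pmax(n - 1L, 0L)
  gRow <- sequence(ng, from = firstRow)
  list(
    start = bs, end = be, chrom = as.character(seqnames(u)),
    nBlocks = as.integer(n), firstRow = firstRow,
    nGaps = as.integer(ng),
    gapFirst = c(0L, cumsum(ng))[seq_along(ng)] + 1L,
    gapStart = be[gRow] + 1L, gapEnd = bs[gRow + 1L] - 1L)
}

# For parallel vectors (readIdx, fs, fe): number of bases of [fs, fe]
# covered by that read's (non-overlapping) blocks.
coveredBases <- function(flat, readIdx, fs, fe) {
  nb <- flat$nBlocks[readIdx]
  rowIdx <- rep.int(seq_along(readIdx), nb)
  blockRow <- sequence(nb, from = flat$firstRow[readIdx])
  ov <- pmax(0L, pmin(flat$end[blockRow], fe[rowIdx]) -
                 pmax(flat$start[blockRow], fs[rowIdx]) + 1L)
  out <- integer(length(readIdx))
  agg <- rowsum(ov, rowIdx)
  out[as.integer(rownames(agg))] <- as.integer(agg[, 1L])
  out
}

# For parallel vectors (readIdx, fs, fe): does the read have an
# inter-block gap whose two junctions both fall within `slack` of the
# feature boundaries?
hasMatchingGap <- function(flat, readIdx, fs, fe, slack) {
  ng <- flat$nGaps[readIdx]
  pairIdx <- rep.int(seq_along(readIdx), ng)
  gapRow <- sequence(ng, from = flat$gapFirst[readIdx])
  hit <- abs(flat$gapStart[gapRow] - fs[pairIdx]) <= slack &
         abs(flat$gapEnd[gapRow] - fe[pairIdx]) <= slack
  out <- logical(length(readIdx))
  if (length(pairIdx)) {
    agg <- rowsum(as.integer(hit), pairIdx)
    out[as.integer(rownames(agg))] <- agg[, 1L] > 0L
  }
  out
}

# Read spans (first to last block) as a GRanges, carrying the read mcols.
readSpans <- function(reads) {
  sp <- unlist(range(reads), use.names = FALSE)
  mcols(sp) <- mcols(reads)
  sp
}

clip01 <- function(x) pmin(1, pmax(0, x))
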