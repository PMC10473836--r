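# Synthetic-data generators: toy genomes with canonical GT..AG introns,
# 3'-anchored long reads with per-intron retention and 5' degradation,
# Pu-seq count tracks under mixtures of canonical and restarted forks,
# and plating counts for the slippage assay. Every generator is
# deterministic given its seed.

.sampleLen <- function(n, range) {
  if (range[1L] > range[2L] || range[1L] < 1L)
    stop("infeasible length range [", range[1L], ", ", range[2L], "]")
  if (range[1L] == range[2L]) rep.int(range[1L], n)
  else sample.int(range[2L] - range[1L] + 1L, n, replace = TRUE) +
    range[1L] - 1L
}

.randomSeq <- function(gcProb) {
  n <- length(gcProb)
  isGC <- runif(n) < gcProb
  half <- runif(n) < 0.5
  out <- character(n)
  out[isGC & half] <- "G"; out[isGC & !half] <- "C"
  out[!isGC & half] <- "A"; out[!isGC & !half] <- "T"
  out
}

#' Simulate a toy genome with annotated multi-exon genes
#'
#' Generates \code{nGenes} genes laid head-to-tail on one chromosome with
#' alternating strands, random exon/intron lengths and canonical GT..AG
#' intron boundaries. Genes named in \code{gcDipGenes} receive a reduced
#' GC fraction in a window spanning the last \code{dipIntronWindow} bases
#' of each intron and the first \code{dipExonWindow} bases of the
#' downstream exon — the sequence signature associated with
#' retention-prone introns — against a uniform GC background elsewhere.
#'
#' @param nGenes number of genes.
#' @param nExonsRange integer range of exons per gene.
#' @param exonLengthRange,intronLengthRange length ranges (bp).
#' @param gcDipGenes character vector of gene ids (subset of the
#'   generated \code{g001..}) given the low-GC 3' splice-site window.
#' @param gcBackground,gcDip GC probability outside/inside the dip window.
#' @param dipIntronWindow,dipExonWindow dip window extent (bp) on the
#'   intron and downstream-exon side of the 3' splice site.
#' @param intergenic spacing between genes (bp).
#' @param chrom chromosome name.
#' @param seed RNG seed (the generator is deterministic given it).
#' @return A [GenomeModel-class]; gene ids are \code{g001}, \code{g002}, ...
#' @examples
#' gm <- simulateGenome(nGenes = 3, seed = 1)
#' introns(gm)
#' @export
simulateGenome <- function(nGenes = 20, nExonsRange = c(2L, 5L),
    exonLengthRange = c(100L, 300L), intronLengthRange = c(40L, 120L),
    gcDipGenes = character(0), gcBackground = 0.40, gcDip = 0.25,
    dipIntronWindow = 40L, dipExonWindow = 100L,
    intergenic = 200L, chrom = "chrI", seed = 1L) {
  if (intronLengthRange[1L] < 4L)
    stop("introns must be at least 4 bp to carry GT..AG boundaries")
  withSeed(seed, {
    ids <- sprintf("g%03d", seq_len(nGenes))
    pieces <- character(0)
    geneList <- vector("list", nGenes)
    offset <- 0L
    for (gi in seq_len(nGenes)) {
      nex <- .sampleLen(1L, nExonsRange)
      exLen <- .sampleLen(nex, exonLengthRange)
      inLen <- if (nex > 1L) .sampleLen(nex - 1L, intronLengthRange)
        else integer(0)
      L <- sum(exLen) + sum(inLen)
      gcProb <- rep.int(gcBackground, L)
      # transcript-direction ("sense") coordinates of exon/intron pieces
      senseStart <- integer(nex); senseEnd <- integer(nex)
      pos <- 0L
      for (k in seq_len(nex)) {
        senseStart[k] <- pos + 1L
        senseEnd[k] <- pos + exLen[k]
        pos <- pos + exLen[k]
        if (k < nex) pos <- pos + inLen[k]
      }
      if (ids[gi] %in% gcDipGenes && nex > 1L) {
        for (k in seq_len(nex - 1L)) {
          intronEnd <- senseStart[k + 1L] - 1L
          dipLo <- max(senseEnd[k] + 1L, intronEnd - dipIntronWindow + 1L)
          dipHi <- min(L, intronEnd + dipExonWindow)
          gcProb[dipLo:dipHi] <- gcDip
        }
      }
      senseSeq <- .randomSeq(gcProb)
      for (k in seq_len(max(nex - 1L, 0L))) {
        is <- senseEnd[k] + 1L
        ie <- senseStart[k + 1L] - 1L
        senseSeq[is:(is + 1L)] <- c("G", "T")
        senseSeq[(ie - 1L):ie] <- c("A", "G")
      }
      senseSeq <- paste(senseSeq, collapse = "")
      str <- if (gi %% 2L == 1L) "+" else "-"
      if (str == "+") {
        genomicSeq <- senseSeq
        exStart <- offset + senseStart
        exEnd <- offset + senseEnd
      } else {
        genomicSeq <- as.character(
          reverseComplement(DNAString(senseSeq)))
        exStart <- offset + L - senseEnd + 1L
        exEnd <- offset + L - senseStart + 1L
      }
      geneList[[gi]] <- Gene(ids[gi], chrom, str,
        IRanges(exStart, exEnd), cdsStartOffset = 0L)
      pieces <- c(pieces, genomicSeq,
        paste(.randomSeq(rep.int(gcBackground, intergenic)), collapse = ""))
      offset <- offset + L + intergenic
    }
    chromSeq <- paste(pieces, collapse = "")
    GenomeModel(setNames(DNAStringSet(chromSeq), chrom), geneList)
  })
}

#' Long-read simulation settings
#'
#' @param depthPerGene mean number of reads per gene (Poisson).
#' @param baseRetention default per-intron retention probability.
#' @param retentionOverrides optional data.frame with columns
#'   \code{gene_id}, \code{intron_index}, \code{condition}, \code{prob}
#'   overriding the base rate for specific introns in a condition.
#' @param p5DegradationMean mean 5'-end truncation length in bases
#'   (exponential); emulates degradation of transcript 5' ends in
#'   polyA-selected cDNA libraries.
#' @param seed base RNG seed; each (condition, replicate) call derives a
#'   distinct stream from it.
#' @return A validated settings list of class \code{ReadSimConfig}.
#' @export
readSimConfig <- function(depthPerGene = 100, baseRetention = 0.02,
    retentionOverrides = NULL, p5DegradationMean = 200, seed = 1L) {
  if (depthPerGene <= 0) stop("depthPerGene must be > 0")
  if (baseRetention < 0 || baseRetention > 1)
    stop("baseRetention must be in [0, 1]")
  if (!is.null(retentionOverrides)) {
    need <- c("gene_id", "intron_index", "condition", "prob")
    if (!all(need %in% names(retentionOverrides)))
      stop("retentionOverrides needs columns: ",
        paste(need, collapse = ", "))
    if (any(retentionOverrides$prob < 0 | retentionOverrides$prob > 1))
      stop("retention probabilities must be in [0, 1]")
  }
  if (p5DegradationMean < 0) stop("p5DegradationMean must be >= 0")
  structure(list(depthPerGene = depthPerGene,
    baseRetention = baseRetention,
    retentionOverrides = retentionOverrides,
    p5DegradationMean = p5DegradationMean,
    seed = as.integer(seed)), class = "ReadSimConfig")
}

.retentionProb <- function(config, geneId, intronIndex, condition) {
  p <- rep.int(config$baseRetention, length(intronIndex))
  ov <- config$retentionOverrides
  if (!is.null(ov)) {
    ov <- ov[ov$gene_id == geneId & ov$condition == condition, ]
    m <- match(intronIndex, ov$intron_index)
    p[!is.na(m)] <- ov$prob[m[!is.na(m)]]
  }
  p
}

#' Simulate 3'-anchored spliced long reads
#'
#' Per gene, draws Poisson(\code{depthPerGene}) reads. Each read retains
#' each intron independently with its retention probability, then loses
#' an exponential number of bases from the transcript 5' end (3'-anchored
#' polyA cDNA), and is emitted as sorted genomic blocks; retained introns
#' merge their flanking exon blocks.
#'
#' @param genome a [GenomeModel-class].
#' @param config a [readSimConfig()].
#' @param condition condition label, e.g. \code{"WT"} or \code{"MUT"};
#'   selects the matching retention overrides.
#' @param replicate replicate number.
#' @param sampleId sample label recorded on the reads.
#' @param seed RNG seed for this call; defaults to a stream derived from
#'   \code{config$seed}, the condition and the replicate.
#' @return A [GenomicRanges::GRangesList] of per-read blocks with
#'   metadata columns \code{read_id}, \code{sample_id}, \code{condition},
#'   \code{replicate}.
#' @export
simulateLongReads <- function(genome, config, condition = "WT",
    replicate = 1L,
    sampleId = sprintf("%s_rep%d", condition, replicate),
    seed = NULL) {
  stopifnot(inherits(config, "ReadSimConfig"))
  if (is.null(seed))
    seed <- (config$seed + 7919L * as.integer(replicate) +
      1299709L * (sum(utf8ToInt(condition)) %% 997L)) %% .Machine$integer.max
  withSeed(seed, {
    outChrom <- character(0)
    outStarts <- list(); outEnds <- list()
    for (gene in genes(genome)) {
      nReads <- rpois(1L, config$depthPerGene)
      if (nReads == 0L) next
      ex <- gene@exons
      nex <- length(ex)
      nInt <- nex - 1L
      ig <- buildIntrons(gene)
      pRet <- if (nInt > 0L)
        .retentionProb(config, gene@geneId, seq_len(nInt), condition)
        else numeric(0)
      exW <- width(ex)
      inW <- width(ig)
      for (r in seq_len(nReads)) {
        retained <- if (nInt > 0L) runif(nInt) < pRet else logical(0)
        # transcript pieces in transcription order: exon1, [intron1], ...
        pieceW <- integer(0); pieceS <- integer(0); pieceE <- integer(0)
        for (k in seq_len(nex)) {
          pieceW <- c(pieceW, exW[k])
          pieceS <- c(pieceS, start(ex)[k]); pieceE <- c(pieceE, end(ex)[k])
          if (k <= nInt && retained[k]) {
            pieceW <- c(pieceW, inW[k])
            pieceS <- c(pieceS, start(ig)[k]); pieceE <- c(pieceE, end(ig)[k])
          }
        }
        L <- sum(pieceW)
        trunc5 <- min(L - 1L,
          if (config$p5DegradationMean > 0)
            as.integer(rexp(1L, 1 / config$p5DegradationMean)) else 0L)
        # drop trunc5 bases from the transcript 5' end
        cum <- cumsum(pieceW)
        firstPiece <- which(cum > trunc5)[1L]
        within <- trunc5 - c(0L, cum)[firstPiece]
        ps <- pieceS[firstPiece:length(pieceS)]
        pe <- pieceE[firstPiece:length(pieceE)]
        if (gene@strand == "+") ps[1L] <- ps[1L] + within
        else pe[1L] <- pe[1L] - within
        o <- order(ps)
        ps <- ps[o]; pe <- pe[o]
        # merge genomically contiguous pieces (retained introns)
        if (length(ps) > 1L) {
          newBlock <- c(TRUE, ps[-1L] != pe[-length(pe)] + 1L)
          grp <- cumsum(newBlock)
          ps <- as.integer(tapply(ps, grp, min))
          pe <- as.integer(tapply(pe, grp, max))
        }
        outChrom <- c(outChrom, gene@chrom)
        outStarts <- c(outStarts, list(ps))
        outEnds <- c(outEnds, list(pe))
      }
    }
    n <- length(outChrom)
    if (n == 0L) {
      reads <- GRangesList()
    } else {
      u <- GRanges(
        seqnames = rep(outChrom, lengths(outStarts)),
        ranges = IRanges(unlist(outStarts), unlist(outEnds)))
      reads <- S4Vectors::split(u,
        rep(seq_len(n), lengths(outStarts)))
      names(reads) <- NULL
    }
    mcols(reads) <- DataFrame(
      read_id = sprintf("%s_r%06d", sampleId, seq_len(n)),
      sample_id = rep.int(sampleId, n),
      condition = rep.int(condition, n),
      replicate = rep.int(as.integer(replicate), n))
    reads
  })
}

#' Fork-mixture settings for Pu-seq track simulation
#'
#' Parameterizes the fork mixture around a polar barrier: with
#' probability \code{arrestProb} a rightward fork arrests at the barrier
#' and restarts as a Pol-delta/Pol-delta fork that runs for
#' \code{restartTractLen} bases; \code{leftwardFraction} of bins are
#' replicated by leftward canonical forks.
#'
#' @param regionStart 1-based start of the simulated region.
#' @param nBins,binSize number and width (bp) of bins.
#' @param barrierPos genomic coordinate of the barrier (must lie inside
#'   the region).
#' @param arrestProb probability a rightward fork arrests and restarts at
#'   the barrier.
#' @param restartTractLen length (bp) of the restarted-fork tract
#'   downstream of the barrier.
#' @param leftwardFraction probability a bin is replicated by a leftward
#'   canonical fork.
#' @param depth mean count per bin per track at fraction 1.
#' @param background additive Poisson noise rate per bin per track.
#' @param chrom chromosome name.
#' @param seed RNG seed.
#' @return A validated settings list of class \code{ForkSimConfig}.
#' @export
forkSimConfig <- function(regionStart = 1L, nBins = 100L, binSize = 300L,
    barrierPos = regionStart + 40L * binSize, arrestProb = 0,
    restartTractLen = 9000L, leftwardFraction = 0, depth = 200,
    background = 0, chrom = "chrI", seed = 1L) {
  regionEnd <- regionStart + nBins * binSize - 1L
  if (barrierPos < regionStart || barrierPos > regionEnd)
    stop("barrierPos must lie inside the simulated region")
  if (arrestProb < 0 || arrestProb > 1)
    stop("arrestProb must be in [0, 1]")
  if (leftwardFraction < 0 || leftwardFraction > 1)
    stop("leftwardFraction must be in [0, 1]")
  if (background < 0) stop("background must be >= 0")
  structure(list(regionStart = as.integer(regionStart),
    nBins = as.integer(nBins), binSize = as.integer(binSize),
    barrierPos = as.integer(barrierPos), arrestProb = arrestProb,
    restartTractLen = as.integer(restartTractLen),
    leftwardFraction = leftwardFraction, depth = depth,
    background = background, chrom = chrom, seed = as.integer(seed)),
    class = "ForkSimConfig")
}

# Expected per-track fractions per bin under the fork mixture.
.forkFractions <- function(config) {
  s <- config$regionStart + (seq_len(config$nBins) - 1L) * config$binSize
  mid <- s + config$binSize / 2
  inTract <- mid > config$barrierPos &
    mid <= config$barrierPos + config$restartTractLen
  pL <- rep.int(config$leftwardFraction, config$nBins)
  pRR <- ifelse(inTract, config$arrestProb * (1 - config$leftwardFraction), 0)
  pR <- 1 - pL - pRR
  list(start = s, end = s + config$binSize - 1L, inTract = inTract,
    delta_top = pL + pRR, delta_bottom = pR + pRR,
    epsilon_top = pR, epsilon_bottom = pL)
}

#' Simulate four Pu-seq count tracks around a polar barrier
#'
#' For each bin, the bin is replicated by a rightward canonical fork,
#' a leftward canonical fork, or (within the restart tract downstream of
#' the barrier) a rightward restarted Pol-delta/Pol-delta fork; the
#' mixture fractions determine the expected strain-by-strand counts:
#' delta/top = leftward + restarted, epsilon/top = rightward,
#' delta/bottom = rightward + restarted, epsilon/bottom = leftward.
#' Counts are Poisson with mean \code{depth * fraction + background}.
#'
#' Because every track is generated at the same per-fraction depth, the
#' returned object carries \code{libraryScale = c(delta = 1, epsilon = 1)}.
#'
#' @param config a [forkSimConfig()].
#' @return A [PuseqTracks-class] over \code{nBins} bins.
#' @export
simulatePuseqCounts <- function(config) {
  stopifnot(inherits(config, "ForkSimConfig"))
  withSeed(config$seed, {
    fr <- .forkFractions(config)
    n <- config$nBins
    cnt <- vapply(.PUSEQ_TRACKS, function(tr)
      as.numeric(rpois(n, config$depth * fr[[tr]] + config$background)),
      numeric(n))
    bins <- GRanges(config$chrom, IRanges(fr$start, fr$end))
    PuseqTracks(bins, cnt, libraryScale = c(delta = 1, epsilon = 1))
  })
}

#' Slippage-assay plating settings
#'
#' @param trueSlipFreq per-cell probability of a slippage reversion.
#' @param nCellsPlated cells in the plated volume before dilution.
#' @param dilutionSelective,dilutionNonselective dilution factors for the
#'   selective (uracil-dropout) and non-selective plates.
#' @param nPlates plates per medium per experiment.
#' @param nExperiments independent experiments.
#' @param seed RNG seed.
#' @return A validated settings list of class \code{SlippageSimConfig}.
#' @export
slippageSimConfig <- function(trueSlipFreq = 5e-4, nCellsPlated = 1e7,
    dilutionSelective = 10, dilutionNonselective = 1e4,
    nPlates = 2L, nExperiments = 3L, seed = 1L) {
  if (trueSlipFreq < 0 || trueSlipFreq > 1)
    stop("trueSlipFreq must be in [0, 1]")
  if (dilutionSelective < 1 || dilutionNonselective < 1)
    stop("dilution factors must be >= 1")
  if (nPlates != 2L)
    stop("the assay plates exactly two plates per medium")
  structure(list(trueSlipFreq = trueSlipFreq, nCellsPlated = nCellsPlated,
    dilutionSelective = dilutionSelective,
    dilutionNonselective = dilutionNonselective,
    nPlates = as.integer(nPlates), nExperiments = as.integer(nExperiments),
    seed = as.integer(seed)), class = "SlippageSimConfig")
}

#' Simulate slippage-assay plate counts
#'
#' Selective plate counts are Poisson with mean
#' \code{nCellsPlated / dilutionSelective * trueSlipFreq} (the Poisson
#' limit of the binomial number of revertants among plated cells);
#' non-selective counts are Poisson with mean
#' \code{nCellsPlated / dilutionNonselective}.
#'
#' @param config a [slippageSimConfig()].
#' @param strain,condition labels recorded on the experiment.
#' @return A [SlippageExperiment-class] with \code{nExperiments} rows.
#' @export
simulateSlippageCounts <- function(config, strain = "sim",
    condition = "simulated") {
  stopifnot(inherits(config, "SlippageSimConfig"))
  withSeed(config$seed, {
    muSel <- config$nCellsPlated / config$dilutionSelective *
      config$trueSlipFreq
    muNon <- config$nCellsPlated / config$dilutionNonselective
    n <- config$nExperiments
    df <- data.frame(
      strain = strain, condition = condition, experiment = seq_len(n),
      selective1 = rpois(n, muSel), selective2 = rpois(n, muSel),
      nonselective1 = rpois(n, muNon), nonselective2 = rpois(n, muNon),
      dilutionSelective = config$dilutionSelective,
      dilutionNonselective = config$dilutionNonselective)
    SlippageExperiment(df)
  })
}
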