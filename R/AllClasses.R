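#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame queryHits subjectHits
#' @importFrom IRanges IRanges start end width shift findOverlaps
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand granges
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement translate
#'   subseq letterFrequency readDNAStringSet writeXStringSet
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
#' @importFrom stats rpois rexp rbinom runif quantile sd var cor cor.test
#'   t.test setNames aggregate
#' @importFrom utils read.delim write.table head tail
NULL

#' Gene model with transcription-ordered exons
#'
#' A single transcript model: an ordered set of exons on one chromosome
#' strand plus the transcript coordinate of the first codon. Exons are
#' stored in transcription order (for minus-strand genes, decreasing
#' genomic coordinate). All coordinates are 1-based closed, the
#' IRanges/GRanges convention; BED (0-based half-open) and GFF3 (1-based
#' closed) are converted at the I/O boundary.
#'
#' @slot geneId character(1) identifier.
#' @slot chrom character(1) chromosome name.
#' @slot strand character(1), \code{"+"} or \code{"-"}.
#' @slot exons [IRanges::IRanges] of exon intervals in transcription order.
#' @slot cdsStartOffset integer(1), 0-based transcript coordinate of the
#'   first base of the first codon (0 = translation starts at the
#'   transcript 5' end).
#'
#' @seealso [Gene()], [buildIntrons()], [isoformSequence()]
#' @exportClass Gene
setClass("Gene",
  representation(
    geneId = "character",
    chrom = "character",
    strand = "character",
    exons = "IRanges",
    cdsStartOffset = "integer"
  )
)

setValidity("Gene", function(object) {
  msgs <- character(0)
  if (length(object@geneId) != 1L || !nzchar(object@geneId))
    msgs <- c(msgs, "geneId must be a single non-empty string")
  if (length(object@chrom) != 1L || !nzchar(object@chrom))
    msgs <- c(msgs, "chrom must be a single non-empty string")
  if (length(object@strand) != 1L || !object@strand %in% c("+", "-"))
    msgs <- c(msgs, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) < 1L)
    msgs <- c(msgs, "gene must have at least one exon")
  if (any(width(ex) < 1L))
    msgs <- c(msgs, "exons must have width >= 1")
  if (length(object@cdsStartOffset) != 1L || is.na(object@cdsStartOffset) ||
      object@cdsStartOffset < 0L)
    msgs <- c(msgs, "cdsStartOffset must be a single integer >= 0")
  if (length(ex) >= 2L && length(object@strand) == 1L &&
      object@strand %in% c("+", "-")) {
    s <- start(ex); e <- end(ex)
    if (object@strand == "+") {
      gaps <- s[-1L] - e[-length(ex)] - 1L
    } else {
      gaps <- s[-length(ex)] - e[-1L] - 1L
    }
    if (any(gaps < 1L))
      msgs <- c(msgs,
        "exons must be non-overlapping, in transcription order, with intron gaps >= 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Gene
#'
#' @param geneId gene/transcript identifier.
#' @param chrom chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons an [IRanges::IRanges] (or 2-column matrix of start, end,
#'   1-based closed) of exon intervals in transcription order: for a
#'   minus-strand gene the first exon is the one with the highest genomic
#'   coordinate.
#' @param cdsStartOffset 0-based transcript coordinate of the first codon.
#'
#' @return A [Gene-class] object.
#' @examples
#' g <- Gene("toy", "chrI", "+", IRanges::IRanges(c(1, 146), c(100, 300)))
#' buildIntrons(g)
#' @export
Gene <- function(geneId, chrom, strand, exons, cdsStartOffset = 0L) {
  if (is.matrix(exons))
    exons <- IRanges(start = exons[, 1L], end = exons[, 2L])
  new("Gene",
    geneId = as.character(geneId), chrom = as.character(chrom),
    strand = as.character(strand), exons = exons,
    cdsStartOffset = as.integer(cdsStartOffset))
}

setMethod("show", "Gene", function(object) {
  cat(sprintf("Gene %s | %s%s | %d exon(s), %d intron(s), cdsStartOffset=%d\n",
    object@geneId, object@chrom, object@strand, length(object@exons),
    max(0L, length(object@exons) - 1L), object@cdsStartOffset))
})

#' Genome model: chromosome sequences plus gene annotation
#'
#' The coordinate backbone shared by all analysis stages: chromosome DNA
#' as a [Biostrings::DNAStringSet] and a list of [Gene-class] transcript
#' models.
#'
#' @slot chromosomes named [Biostrings::DNAStringSet].
#' @slot genes named list of [Gene-class] objects (names = gene ids).
#'
#' @seealso [GenomeModel()], [simulateGenome()], [introns()]
#' @exportClass GenomeModel
setClass("GenomeModel",
  representation(chromosomes = "DNAStringSet", genes = "list")
)

setValidity("GenomeModel", function(object) {
  msgs <- character(0)
  nm <- names(object@chromosomes)
  if (length(object@chromosomes) && (is.null(nm) || anyDuplicated(nm)))
    msgs <- c(msgs, "chromosome names must be present and unique")
  bad <- Biostrings::letterFrequency(object@chromosomes, "ACGTN") !=
    Biostrings::width(object@chromosomes)
  if (any(bad))
    msgs <- c(msgs, "chromosome sequences must use alphabet {A,C,G,T,N}")
  for (g in object@genes) {
    if (!is(g, "Gene")) {
      msgs <- c(msgs, "genes must be a list of Gene objects")
      break
    }
    if (!g@chrom %in% nm) {
      msgs <- c(msgs, sprintf("gene %s references unknown chromosome %s",
        g@geneId, g@chrom))
      next
    }
    if (min(start(g@exons)) < 1L ||
        max(end(g@exons)) > Biostrings::width(object@chromosomes[g@chrom]))
      msgs <- c(msgs, sprintf("gene %s extends beyond chromosome %s",
        g@geneId, g@chrom))
  }
  ids <- vapply(object@genes, function(g) g@geneId, character(1))
  if (anyDuplicated(ids))
    msgs <- c(msgs, "gene ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenomeModel
#'
#' @param chromosomes named character vector or [Biostrings::DNAStringSet]
#'   of chromosome sequences.
#' @param genes list of [Gene-class] objects.
#' @return A [GenomeModel-class] object; the gene list is named by gene id.
#' @export
GenomeModel <- function(chromosomes, genes = list()) {
  if (!is(chromosomes, "DNAStringSet"))
    chromosomes <- DNAStringSet(chromosomes)
  names(genes) <- vapply(genes, function(g) g@geneId, character(1))
  new("GenomeModel", chromosomes = chromosomes, genes = genes)
}

setMethod("show", "GenomeModel", function(object) {
  cat(sprintf("GenomeModel | %d chromosome(s) (%d bp) | %d gene(s)\n",
    length(object@chromosomes), sum(Biostrings::width(object@chromosomes)),
    length(object@genes)))
})

#' Pu-seq count tracks for two polymerase-mutant strains
#'
#' Binned strand-specific ribonucleotide counts for the Pol-delta and
#' Pol-epsilon mutant strains, stored as a
#' [SummarizedExperiment::RangedSummarizedExperiment] with one assay
#' \code{"counts"} whose four columns are the (strain, strand) tracks
#' \code{delta_top}, \code{delta_bottom}, \code{epsilon_top},
#' \code{epsilon_bottom}. \code{metadata(x)$libraryScale}, when present,
#' is a named numeric factor per strain (\code{delta}, \code{epsilon})
#' applied before usage ratios are formed; when absent, [computeUsage()]
#' equalizes the two strains' totals over the analysed region.
#'
#' @seealso [PuseqTracks()], [simulatePuseqCounts()], [computeUsage()]
#' @exportClass PuseqTracks
setClass("PuseqTracks", contains = "RangedSummarizedExperiment")

.PUSEQ_TRACKS <- c("delta_top", "delta_bottom", "epsilon_top", "epsilon_bottom")

setValidity("PuseqTracks", function(object) {
  msgs <- character(0)
  a <- SummarizedExperiment::assayNames(object)
  if (!identical(a, "counts"))
    return("PuseqTracks must have exactly one assay named 'counts'")
  cnt <- assay(object, "counts")
  if (!identical(colnames(cnt), .PUSEQ_TRACKS))
    msgs <- c(msgs, sprintf("count columns must be %s",
      paste(.PUSEQ_TRACKS, collapse = ", ")))
  if (any(cnt < 0, na.rm = TRUE))
    msgs <- c(msgs, "counts must be non-negative")
  b <- rowRanges(object)
  if (length(b) > 1L) {
    o <- order(seqnames(b), start(b))
    if (!identical(o, seq_along(b)))
      msgs <- c(msgs, "bins must be sorted")
    same <- as.character(seqnames(b))[-length(b)] ==
      as.character(seqnames(b))[-1L]
    if (any(same & (start(b)[-1L] <= end(b)[-length(b)])))
      msgs <- c(msgs, "bins must be non-overlapping")
  }
  ls <- metadata(object)$libraryScale
  if (!is.null(ls)) {
    if (!is.numeric(ls) || !all(c("delta", "epsilon") %in% names(ls)) ||
        any(ls[c("delta", "epsilon")] <= 0))
      msgs <- c(msgs, "libraryScale must be positive and named delta/epsilon")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PuseqTracks object
#'
#' @param bins [GenomicRanges::GRanges] of genomic bins (sorted,
#'   non-overlapping).
#' @param counts numeric matrix, \code{length(bins)} rows and columns
#'   \code{delta_top}, \code{delta_bottom}, \code{epsilon_top},
#'   \code{epsilon_bottom}.
#' @param libraryScale optional named numeric, per-strain scale factors
#'   (\code{c(delta=, epsilon=)}) known from library normalization. When
#'   \code{NULL}, [computeUsage()] equalizes strain totals over the region.
#' @return A [PuseqTracks-class] object.
#' @export
PuseqTracks <- function(bins, counts, libraryScale = NULL) {
  cd <- DataFrame(
    strain = c("delta", "delta", "epsilon", "epsilon"),
    strand = c("top", "bottom", "top", "bottom"),
    row.names = .PUSEQ_TRACKS)
  counts <- as.matrix(counts)
  colnames(counts) <- colnames(counts) %||% .PUSEQ_TRACKS
  se <- SummarizedExperiment(
    assays = list(counts = counts), rowRanges = bins, colData = cd)
  obj <- new("PuseqTracks", se)
  if (!is.null(libraryScale)) metadata(obj)$libraryScale <- libraryScale
  validObject(obj)
  obj
}

setMethod("show", "PuseqTracks", function(object) {
  cat(sprintf(
    "PuseqTracks | %d bins | strain totals: delta=%.0f epsilon=%.0f%s\n",
    nrow(object),
    sum(assay(object)[, c("delta_top", "delta_bottom")]),
    sum(assay(object)[, c("epsilon_top", "epsilon_bottom")]),
    if (is.null(metadata(object)$libraryScale)) "" else " | libraryScale set"))
})

#' Replication-slippage plating experiment
#'
#' Colony counts for the slippage reversion assay: per independent
#' experiment, two selective (uracil-dropout) plates and two non-selective
#' plates, each pair with its dilution factor. Reversion frequency is the
#' dilution-corrected ratio of selective to non-selective counts.
#'
#' @slot counts data.frame with columns \code{strain}, \code{condition},
#'   \code{experiment}, \code{selective1}, \code{selective2},
#'   \code{nonselective1}, \code{nonselective2}, \code{dilutionSelective},
#'   \code{dilutionNonselective}.
#'
#' @seealso [SlippageExperiment()], [reversionFrequency()],
#'   [simulateSlippageCounts()]
#' @exportClass SlippageExperiment
setClass("SlippageExperiment", representation(counts = "data.frame"))

.SLIP_COLS <- c("strain", "condition", "experiment",
  "selective1", "selective2", "nonselective1", "nonselective2",
  "dilutionSelective", "dilutionNonselective")

setValidity("SlippageExperiment", function(object) {
  df <- object@counts
  msgs <- character(0)
  miss <- setdiff(.SLIP_COLS, names(df))
  if (length(miss))
    return(sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  cnt <- as.matrix(df[, c("selective1", "selective2",
    "nonselective1", "nonselective2")])
  if (any(cnt < 0) || any(cnt != round(cnt)))
    msgs <- c(msgs, "plate counts must be non-negative integers")
  if (any(df$dilutionSelective < 1) || any(df$dilutionNonselective < 1))
    msgs <- c(msgs, "dilution factors must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SlippageExperiment
#'
#' @param counts data.frame of plate counts; see
#'   [SlippageExperiment-class] for the required columns.
#' @return A [SlippageExperiment-class] object.
#' @export
SlippageExperiment <- function(counts) {
  new("SlippageExperiment", counts = as.data.frame(counts))
}

setMethod("show", "SlippageExperiment", function(object) {
  cat(sprintf("SlippageExperiment | %d experiment(s), %d condition(s)\n",
    nrow(object@counts), length(unique(object@counts$condition))))
})

#' @describeIn SlippageExperiment accessor for the plate-count table.
#' @param x a \code{SlippageExperiment}.
#' @export
plateCounts <- function(x) {
  stopifnot(is(x, "SlippageExperiment"))
  x@counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
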