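# Accessors and transcript-model operations shared by all stages.

#' @rdname GenomeModel-class
#' @param x a \code{GenomeModel}.
#' @export
chromosomes <- function(x) {
  stopifnot(is(x, "GenomeModel"))
  x@chromosomes
}

#' @rdname GenomeModel-class
#' @export
genes <- function(x) {
  stopifnot(is(x, "GenomeModel"))
  x@genes
}

#' @rdname GenomeModel-class
#' @export
geneIds <- function(x) names(genes(x))

#' @rdname GenomeModel-class
#' @param geneId a gene id present in the model.
#' @export
getGene <- function(x, geneId) {
  g <- genes(x)[[geneId]]
  if (is.null(g))
    stop("unknown gene_id '", geneId, "': not in the genome annotation")
  g
}

#' @rdname Gene-class
#' @param x a \code{Gene}.
#' @export
exons <- function(x) {
  stopifnot(is(x, "Gene"))
  x@exons
}

#' Gene footprints as a GRanges
#'
#' One range per gene spanning its first to last exon, with \code{gene_id}
#' metadata column. Used for read-to-gene assignment.
#'
#' @param genome a [GenomeModel-class].
#' @return A [GenomicRanges::GRanges], one range per gene.
#' @export
geneRanges <- function(genome) {
  gl <- genes(genome)
  if (!length(gl))
    return(GRanges(gene_id = character(0)))
  gr <- GRanges(
    seqnames = vapply(gl, function(g) g@chrom, character(1)),
    ranges = IRanges(
      start = vapply(gl, function(g) min(start(g@exons)), integer(1)),
      end = vapply(gl, function(g) max(end(g@exons)), integer(1))),
    strand = vapply(gl, function(g) g@strand, character(1)),
    gene_id = names(gl))
  unname(gr)
}

#' Enumerate the introns of a gene
#'
#' One intron per gap between consecutive exons, indexed 1..n-1 in
#' transcription order: for a minus-strand gene intron 1 is the gap
#' nearest the transcription start, i.e. the one with the highest genomic
#' coordinate. Each intron carries its flanking exons ("downstream" =
#' next exon in transcription direction) as metadata columns.
#'
#' @param gene a [Gene-class].
#' @return A [GenomicRanges::GRanges] in transcription order with
#'   metadata columns \code{gene_id}, \code{intron_index},
#'   \code{up_start}, \code{up_end}, \code{down_start}, \code{down_end}
#'   (1-based closed flanking-exon coordinates). A single-exon gene
#'   yields an empty GRanges.
#' @examples
#' g <- Gene("toy", "chrI", "+", IRanges::IRanges(c(1, 146), c(100, 300)))
#' buildIntrons(g)  # one 45-bp intron at 101..145
#' @export
buildIntrons <- function(gene) {
  stopifnot(is(gene, "Gene"))
  ex <- gene@exons
  n <- length(ex)
  empty <- GRanges(gene_id = character(0), intron_index = integer(0),
    up_start = integer(0), up_end = integer(0),
    down_start = integer(0), down_end = integer(0))
  if (n < 2L) return(empty)
  up <- ex[-n]     # exon preceding the intron in transcription order
  down <- ex[-1L]  # exon following it
  if (gene@strand == "+") {
    istart <- end(up) + 1L
    iend <- start(down) - 1L
  } else {
    istart <- end(down) + 1L
    iend <- start(up) - 1L
  }
  GRanges(
    seqnames = gene@chrom,
    ranges = IRanges(start = istart, end = iend),
    strand = gene@strand,
    gene_id = gene@geneId,
    intron_index = seq_len(n - 1L),
    up_start = start(up), up_end = end(up),
    down_start = start(down), down_end = end(down))
}

#' All introns of a genome model
#'
#' @param genome a [GenomeModel-class].
#' @return A [GenomicRanges::GRanges] concatenating [buildIntrons()] over
#'   all genes (transcription order within gene).
#' @export
introns <- function(genome) {
  stopifnot(is(genome, "GenomeModel"))
  grl <- lapply(unname(genes(genome)), buildIntrons)
  if (!length(grl))
    return(buildIntrons(Gene("x", "x", "+", IRanges(1, 1)))[0])
  do.call(c, grl)
}

#' Transcript isoform specification
#'
#' A gene id plus the set of intron indices retained in the isoform.
#'
#' @param geneId gene id.
#' @param retainedIntrons integer vector of retained intron indices
#'   (1-based, transcription order); empty for the fully spliced mRNA.
#' @return An object of class \code{IsoformSpec} (a validated list).
#' @export
IsoformSpec <- function(geneId, retainedIntrons = integer(0)) {
  retainedIntrons <- sort(unique(as.integer(retainedIntrons)))
  if (any(retainedIntrons < 1L))
    stop("retained intron indices must be >= 1")
  structure(list(geneId = as.character(geneId),
    retainedIntrons = retainedIntrons), class = "IsoformSpec")
}

.checkIsoform <- function(gene, spec) {
  nInt <- length(gene@exons) - 1L
  if (length(spec$retainedIntrons) && max(spec$retainedIntrons) > nInt)
    stop(sprintf("gene %s has %d intron(s); retained index %d is invalid",
      gene@geneId, nInt, max(spec$retainedIntrons)))
}

#' Construct an isoform's transcript sequence
#'
#' Concatenates exon sequences in transcription order with retained-intron
#' sequences inserted at their positions; minus-strand transcripts are
#' reverse-complemented so the result always reads 5' to 3'.
#'
#' @param genome a [GenomeModel-class].
#' @param spec an [IsoformSpec()].
#' @return A character scalar, the transcript sequence 5'->3'.
#' @export
isoformSequence <- function(genome, spec) {
  stopifnot(inherits(spec, "IsoformSpec"))
  gene <- getGene(genome, spec$geneId)
  .checkIsoform(gene, spec)
  pieces <- gene@exons
  if (length(spec$retainedIntrons)) {
    ig <- buildIntrons(gene)
    keep <- ig[mcols(ig)$intron_index %in% spec$retainedIntrons]
    pieces <- c(pieces, IRanges(start(keep), end(keep)))
  }
  # genomic-ascending concatenation is the plus-strand pre-mRNA selection;
  # retained introns keep the selection contiguous where they occur
  pieces <- pieces[order(start(pieces))]
  chromSeq <- chromosomes(genome)[[gene@chrom]]
  seqs <- Biostrings::extractAt(chromSeq, pieces)
  out <- do.call(Biostrings::xscat, as.list(seqs))
  if (gene@strand == "-") out <- reverseComplement(out)
  as.character(out)
}

.translateCds <- function(txSeq, cdsStartOffset) {
  cds <- substr(txSeq, cdsStartOffset + 1L, nchar(txSeq))
  cds <- substr(cds, 1L, 3L * (nchar(cds) %/% 3L))
  if (nchar(cds) < 3L) return("")
  aa <- as.character(suppressWarnings(
    translate(DNAString(cds), if.fuzzy.codon = "X")))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) substr(aa, 1L, stop_at - 1L) else aa
}

#' Compare the proteins of a spliced and an intron-retained isoform
#'
#' Translates both isoforms from the annotated CDS start using the
#' standard genetic code (stopping at the first stop codon) and reports
#' whether the retention is in frame, how many residues it inserts, and
#' where the insertion falls. Retention is in frame iff the total
#' retained intron length is a multiple of 3 and no premature stop codon
#' is introduced.
#'
#' @param genome a [GenomeModel-class].
#' @param specSpliced [IsoformSpec()] for the reference (spliced) isoform.
#' @param specRetained [IsoformSpec()] for the intron-retained isoform;
#'   must be for the same gene.
#' @return A list with elements \code{in_frame} (logical),
#'   \code{inserted_residues} (integer; negative if the retained protein
#'   is truncated), \code{insertion_position} (number of leading residues
#'   shared with the spliced protein before divergence) and
#'   \code{truncated} (logical, \code{TRUE} when retention introduces a
#'   premature stop).
#' @examples
#' # a 45-bp stop-free intron retained between codons 202 and 203 inserts
#' # 15 residues in frame (see the package vignette for the construction)
#' @export
compareIsoformProteins <- function(genome, specSpliced, specRetained) {
  stopifnot(inherits(specSpliced, "IsoformSpec"),
    inherits(specRetained, "IsoformSpec"))
  if (!identical(specSpliced$geneId, specRetained$geneId))
    stop("both isoform specs must refer to the same gene")
  gene <- getGene(genome, specSpliced$geneId)
  .checkIsoform(gene, specRetained)
  ig <- buildIntrons(gene)
  extra <- setdiff(specRetained$retainedIntrons, specSpliced$retainedIntrons)
  retainedLen <- sum(width(ig)[mcols(ig)$intron_index %in% extra])

  protSpliced <- .translateCds(isoformSequence(genome, specSpliced),
    gene@cdsStartOffset)
  protRetained <- .translateCds(isoformSequence(genome, specRetained),
    gene@cdsStartOffset)

  inserted <- nchar(protRetained) - nchar(protSpliced)
  truncated <- nchar(protRetained) < nchar(protSpliced)
  inFrame <- (retainedLen %% 3L == 0L) && !truncated

  # longest common prefix = last shared residue before divergence
  nmin <- min(nchar(protSpliced), nchar(protRetained))
  pos <- 0L
  if (nmin > 0L) {
    a <- utf8ToInt(substr(protSpliced, 1L, nmin))
    b <- utf8ToInt(substr(protRetained, 1L, nmin))
    d <- which(a != b)
    pos <- if (length(d)) d[1L] - 1L else nmin
  }
  list(in_frame = inFrame, inserted_residues = as.integer(inserted),
    insertion_position = as.integer(pos), truncated = truncated)
}
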