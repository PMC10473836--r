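# Readers/writers for the standard formats the pipeline touches.
# On-disk conventions: FASTA; GFF3 1-based closed; BED12 0-based half-open;
# bedGraph 0-based half-open. Everything is converted to 1-based closed
# IRanges/GRanges coordinates at this boundary.

#' Read a FASTA file into a named sequence set
#'
#' Sequence names are truncated at the first whitespace; duplicate names
#' are an error.
#'
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readFasta <- function(path) {
  seqs <- readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence names in FASTA: ",
      paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet].
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon (and, when present, CDS) features and returns one
#' [Gene-class] per mRNA, identified by the mRNA \code{ID}. Exons are
#' attached by \code{Parent} and sorted in transcription order; GFF3
#' 1-based closed coordinates map directly onto the internal convention.
#' The CDS start offset is derived from the 5'-most CDS feature in
#' transcript coordinates (0 when no CDS is annotated).
#'
#' @param path GFF3 file.
#' @return Named list of [Gene-class] objects.
#' @export
readGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  mrna <- gr[type %in% c("mRNA", "transcript")]
  ex <- gr[type == "exon"]
  cds <- gr[type == "CDS"]
  if (length(ex)) {
    npar <- lengths(ex$Parent) == 0L
    if (any(npar))
      stop("exon feature without Parent attribute in ", path)
  }
  exParent <- if (length(ex))
    vapply(as.list(ex$Parent), `[`, character(1), 1L) else character(0)
  cdsParent <- if (length(cds))
    vapply(as.list(cds$Parent), `[`, character(1), 1L) else character(0)
  out <- list()
  for (i in seq_along(mrna)) {
    id <- mrna$ID[i]
    str <- as.character(strand(mrna))[i]
    myex <- ex[exParent == id]
    if (!length(myex))
      stop("mRNA ", id, " has no exon features")
    o <- order(start(myex))
    myex <- myex[o]
    if (length(myex) > 1L &&
        any(start(myex)[-1L] <= end(myex)[-length(myex)]))
      stop("overlapping exons within mRNA ", id)
    if (str == "-") myex <- rev(myex)
    exIR <- IRanges(start(myex), end(myex))
    cdsOff <- 0L
    mycds <- cds[cdsParent == id]
    if (length(mycds)) {
      cdsStartGenomic <- if (str == "+") min(start(mycds)) else max(end(mycds))
      cdsOff <- .genomicToTranscript(cdsStartGenomic, exIR, str) - 1L
    }
    out[[as.character(id)]] <- Gene(
      geneId = as.character(id),
      chrom = as.character(seqnames(mrna))[i],
      strand = str, exons = exIR, cdsStartOffset = cdsOff)
  }
  out
}

# genomic position -> 1-based transcript coordinate along exons in
# transcription order; NA when the position is intronic/outside
.genomicToTranscript <- function(pos, exonsTx, str) {
  offset <- 0L
  for (i in seq_along(exonsTx)) {
    s <- start(exonsTx)[i]; e <- end(exonsTx)[i]
    if (pos >= s && pos <= e) {
      within <- if (str == "+") pos - s else e - pos
      return(offset + within + 1L)
    }
    offset <- offset + (e - s + 1L)
  }
  NA_integer_
}

#' Write a GenomeModel's annotation to GFF3
#'
#' Emits gene, mRNA, exon and (when \code{cdsStartOffset} targets a
#' position inside the transcript) CDS features, 1-based closed.
#'
#' @param genome a [GenomeModel-class].
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeGff3 <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes(genome)) {
    lo <- min(start(g@exons)); hi <- max(end(g@exons))
    writeLines(sprintf("%s\tforksplice\tgene\t%d\t%d\t.\t%s\t.\tID=%s_g",
      g@chrom, lo, hi, g@strand, g@geneId), con)
    writeLines(sprintf(
      "%s\tforksplice\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s_g",
      g@chrom, lo, hi, g@strand, g@geneId, g@geneId), con)
    exTx <- g@exons
    exGenomic <- exTx[order(start(exTx))]
    for (i in seq_along(exGenomic))
      writeLines(sprintf(
        "%s\tforksplice\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
        g@chrom, start(exGenomic)[i], end(exGenomic)[i], g@strand,
        g@geneId, i, g@geneId), con)
    cdsg <- .transcriptToGenomic(g@cdsStartOffset + 1L, exTx, g@strand)
    if (!is.na(cdsg)) {
      # a single CDS anchor feature carrying the start codon position
      writeLines(sprintf(
        "%s\tforksplice\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
        g@chrom, cdsg, cdsg, g@strand, g@geneId, g@geneId), con)
    }
  }
  invisible(path)
}

.transcriptToGenomic <- function(txPos, exonsTx, str) {
  offset <- 0L
  for (i in seq_along(exonsTx)) {
    w <- width(exonsTx)[i]
    if (txPos <= offset + w) {
      within <- txPos - offset - 1L
      return(if (str == "+") start(exonsTx)[i] + within
             else end(exonsTx)[i] - within)
    }
    offset <- offset + w
  }
  NA_integer_
}

#' Read spliced long-read alignments from BED12
#'
#' Reconstructs each read's aligned blocks from blockStarts/blockSizes as
#' absolute 1-based closed genomic intervals and attaches the sample
#' metadata that travels with the file.
#'
#' @param path BED12 file.
#' @param sampleId,condition,replicate sample metadata recorded on every
#'   read; \code{condition} is typically \code{"WT"} or \code{"MUT"}.
#' @return A [GenomicRanges::GRangesList], one element per read holding
#'   its blocks (sorted, non-overlapping), with metadata columns
#'   \code{read_id}, \code{sample_id}, \code{condition}, \code{replicate}.
#' @export
readBed12 <- function(path, sampleId = "sample1", condition = "WT",
                      replicate = 1L) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks))
    stop("not a BED12 file (no block structure): ", path)
  reads <- rtracklayer::blocks(gr)  # absolute per-read block GRanges
  ids <- gr$name
  if (is.null(ids) || any(is.na(ids)))
    ids <- sprintf("read%06d", seq_along(gr))
  names(reads) <- NULL
  mcols(reads) <- DataFrame(read_id = ids, sample_id = sampleId,
    condition = condition, replicate = as.integer(replicate))
  reads
}

#' Write reads to BED12
#'
#' @param reads [GenomicRanges::GRangesList] of per-read blocks, as
#'   returned by [readBed12()] or [simulateLongReads()].
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeBed12 <- function(reads, path) {
  nm <- mcols(reads)$read_id %||% sprintf("read%06d", seq_along(reads))
  out <- reads
  names(out) <- nm
  mcols(out) <- NULL
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}

#' Read a 4-column bedGraph into genomic bins
#'
#' Accepts unsorted input; returns sorted bins. Overlapping bins are an
#' error. bedGraph 0-based half-open intervals are converted to 1-based
#' closed.
#'
#' @param path bedGraph file.
#' @return A sorted [GenomicRanges::GRanges] with metadata column
#'   \code{score} (the bin value).
#' @export
readBedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- BiocGenerics::sort(gr)
  if (length(gr) > 1L) {
    same <- as.character(seqnames(gr))[-length(gr)] ==
      as.character(seqnames(gr))[-1L]
    if (any(same & start(gr)[-1L] <= end(gr)[-length(gr)]))
      stop("overlapping bins in bedGraph: ", path)
  }
  gr
}

#' Write genomic bins to bedGraph
#'
#' @param bins [GenomicRanges::GRanges] with a numeric \code{score}
#'   metadata column (or a separate \code{score} argument).
#' @param path output file.
#' @param score optional numeric vector overriding \code{bins$score}.
#' @return Invisibly, \code{path}.
#' @export
writeBedgraph <- function(bins, path, score = NULL) {
  if (!is.null(score)) bins$score <- score
  bins <- BiocGenerics::sort(bins)
  rtracklayer::export(bins, path, format = "bedGraph")
  invisible(path)
}

#' Read a sample manifest and load the BED12 files it lists
#'
#' The manifest is tab-delimited with columns \code{path},
#' \code{sample_id}, \code{condition}, \code{replicate}; relative paths
#' resolve against the manifest's directory.
#'
#' @param path manifest TSV.
#' @return A single [GenomicRanges::GRangesList] concatenating all
#'   samples' reads, metadata columns as in [readBed12()].
#' @export
readSampleManifest <- function(path) {
  mf <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("path", "sample_id", "condition", "replicate")
  miss <- setdiff(need, names(mf))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  base <- dirname(normalizePath(path))
  parts <- lapply(seq_len(nrow(mf)), function(i) {
    p <- mf$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    readBed12(p, mf$sample_id[i], mf$condition[i], mf$replicate[i])
  })
  do.call(c, parts)
}
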