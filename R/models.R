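#' Construct a transcript model
#'
#' A transcript model is an exon-structured record of one transcript on a
#' genome. All internal coordinates in this package are 0-based, half-open;
#' conversion to and from 1-based closed conventions happens only at format
#' boundaries (GTF/SAM readers and writers).
#'
#' @param transcript_id character scalar.
#' @param gene_id character scalar or `NA` when the transcript is not (yet)
#'   assigned to a gene.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column numeric matrix (start, end) of exon intervals,
#'   0-based half-open. Rows are sorted by start; exons must not touch or
#'   overlap (consecutive exons are separated by at least a 1-bp intron).
#' @return An object of class `TranscriptModel`.
#' @examples
#' t1 <- transcript_model("T1", "G1", "chr1", "+", cbind(c(100, 300), c(200, 400)))
#' tss_of(t1)
#' @export
transcript_model <- function(transcript_id, gene_id = NA_character_, chrom,
                             strand, exons) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L)
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L)
    stop("transcript '", transcript_id, "': exon list is empty")
  if (!strand %in% c("+", "-"))
    stop("transcript '", transcript_id, "': strand must be '+' or '-'")
  exons <- exons[order(exons[, 1L], exons[, 2L]), , drop = FALSE]
  if (any(exons[, 1L] >= exons[, 2L]))
    stop("transcript '", transcript_id, "': exon with start >= end")
  if (nrow(exons) > 1L) {
    gaps <- exons[-1L, 1L] - exons[-nrow(exons), 2L]
    if (any(gaps < 1))
      stop("transcript '", transcript_id,
           "': exons overlap or touch (no intron between them)")
  }
  structure(list(transcript_id = transcript_id,
                 gene_id = gene_id,
                 chrom = as.character(chrom),
                 strand = strand,
                 exons = exons),
            class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (%s) %s:%s %d exon(s) [%d-%d)\n",
              x$transcript_id, ifelse(is.na(x$gene_id), "-", x$gene_id),
              x$chrom, x$strand, nrow(x$exons),
              min(x$exons[, 1L]), max(x$exons[, 2L])))
  invisible(x)
}

#' Construct a gene model
#'
#' @param gene_id character scalar.
#' @param biotype one of `"protein_coding"`, `"noncoding"`, `"other"`.
#' @param transcripts list of [transcript_model()] objects, all on the same
#'   chromosome and strand.
#' @return An object of class `GeneModel` with a `span` field covering all
#'   member exons.
#' @export
gene_model <- function(gene_id, biotype = c("protein_coding", "noncoding",
                                            "other"), transcripts) {
  biotype <- match.arg(biotype)
  stopifnot(length(transcripts) >= 1L)
  chroms <- unique(vapply(transcripts, `[[`, "", "chrom"))
  strands <- unique(vapply(transcripts, `[[`, "", "strand"))
  if (length(chroms) != 1L || length(strands) != 1L)
    stop("gene '", gene_id, "': transcripts span multiple chromosomes/strands")
  starts <- vapply(transcripts, function(t) min(t$exons[, 1L]), 0)
  ends <- vapply(transcripts, function(t) max(t$exons[, 2L]), 0)
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  structure(list(gene_id = gene_id,
                 biotype = biotype,
                 chrom = chroms,
                 strand = strands,
                 transcripts = transcripts,
                 span = c(start = min(starts), end = max(ends))),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s) %s:%s %d transcript(s) span [%d-%d)\n",
              x$gene_id, x$biotype, x$chrom, x$strand,
              length(x$transcripts), x$span[["start"]], x$span[["end"]]))
  invisible(x)
}

#' Construct an aligned segment of a (possibly chimeric) read
#'
#' One contiguous piece of a long-read alignment: a query interval mapped to
#' a genomic interval. Both intervals are 0-based half-open. Query
#' coordinates always refer to the original (forward) read orientation.
#'
#' @param query_start,query_end interval on the read.
#' @param chrom,strand,target_start,target_end genomic locus.
#' @param mapq mapping quality (`NA` when unknown, e.g. from PAF without it).
#' @return An object of class `AlignedSegment`.
#' @export
aligned_segment <- function(query_start, query_end, chrom, strand,
                            target_start, target_end, mapq = NA_real_) {
  if (query_start >= query_end) stop("segment with query_start >= query_end")
  if (target_start >= target_end) stop("segment with target_start >= target_end")
  structure(list(query_start = query_start, query_end = query_end,
                 chrom = as.character(chrom), strand = strand,
                 target_start = target_start, target_end = target_end,
                 mapq = mapq),
            class = "AlignedSegment")
}

#' Construct a chimeric alignment record
#'
#' One long-read query together with all of its aligned segments. A read that
#' maps in pieces to two or more separated loci is the raw signal of a fusion
#' transcript; a read with zero segments is unaligned.
#'
#' @param query_id read identifier.
#' @param query_length read length in bp (> 0).
#' @param segments list of [aligned_segment()] objects; each segment's query
#'   interval must lie within `[0, query_length]`.
#' @return An object of class `ChimericAlignment`.
#' @export
chimeric_alignment <- function(query_id, query_length, segments = list()) {
  if (query_length <= 0) stop("query_length must be > 0")
  for (s in segments) {
    if (s$query_start < 0 || s$query_end > query_length)
      stop("read '", query_id, "': segment query interval outside [0, ",
           query_length, ")")
  }
  structure(list(query_id = query_id,
                 query_length = query_length,
                 segments = segments),
            class = "ChimericAlignment")
}

#' @export
print.ChimericAlignment <- function(x, ...) {
  cat(sprintf("ChimericAlignment %s len=%d with %d segment(s)\n",
              x$query_id, x$query_length, length(x$segments)))
  invisible(x)
}

#' Construct a peak set
#'
#' A named collection of genomic intervals (e.g. CAGE tag clusters or
#' H3K4me3 peaks), stored per chromosome as sorted 0-based half-open
#' intervals.
#'
#' @param name label of the mark or assay.
#' @param intervals data.frame with columns `chrom`, `start`, `end`.
#' @return An object of class `PeakSet`.
#' @export
peak_set <- function(name, intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) && any(intervals$start >= intervals$end))
    stop("peak set '", name, "': interval with start >= end")
  intervals <- intervals[order(intervals$chrom, intervals$start,
                               intervals$end), , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(name = name, intervals = intervals), class = "PeakSet")
}

#' Isoform identity key of a transcript
#'
#' Two transcripts are the same isoform when they share chromosome, strand
#' and the full ordered chain of intron boundaries; variation at the 5' and
#' 3' ends is ignored. Mono-exonic transcripts have no introns, so their key
#' uses the exact exon bounds instead. Keys are plain strings so isoform
#' sets can be compared across samples with ordinary set operations.
#'
#' @param t a [transcript_model()].
#' @return character scalar key; equal keys iff identical splicing structure.
#' @examples
#' t <- transcript_model("T1", "G1", "chr1", "+", cbind(c(100, 300), c(200, 400)))
#' intron_chain_key(t)   # records the single intron [200,300)
#' @export
intron_chain_key <- function(t) {
  n <- nrow(t$exons)
  if (n == 1L) {
    return(paste(t$chrom, t$strand, "mono",
                 t$exons[1L, 1L], t$exons[1L, 2L], sep = ":"))
  }
  introns <- paste(t$exons[-n, 2L], t$exons[-1L, 1L], sep = "-")
  paste(t$chrom, t$strand, paste(introns, collapse = ";"), sep = ":")
}

#' Introns of a transcript
#'
#' @param t a [transcript_model()].
#' @return two-column matrix (start, end) of intron intervals, 0-based
#'   half-open; zero rows for mono-exonic transcripts.
#' @export
introns_of <- function(t) {
  n <- nrow(t$exons)
  if (n == 1L)
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  cbind(start = t$exons[-n, 2L], end = t$exons[-1L, 1L])
}

#' Transcription start site of a transcript
#'
#' The TSS is the 5'-most transcribed genomic base of the transcript
#' structure: the first exon's start on the plus strand, and the last base
#' (end - 1 in half-open coordinates) of the last exon on the minus strand.
#'
#' @param t a [transcript_model()].
#' @return 0-based genomic position of the TSS (always inside an exon).
#' @export
tss_of <- function(t) {
  unname(if (t$strand == "+") t$exons[1L, 1L]
         else t$exons[nrow(t$exons), 2L] - 1)
}

#' Flatten a gene annotation into a transcript list
#'
#' @param genes list of [gene_model()] objects.
#' @return unnamed list of all member [transcript_model()] objects.
#' @export
annotation_transcripts <- function(genes) {
  unlist(lapply(genes, `[[`, "transcripts"), recursive = FALSE, use.names = FALSE)
}

# GRanges of all exons of a transcript list, with transcript/gene metadata.
# Used by the overlap-based classifiers; not exported.
exons_granges <- function(transcripts) {
  n_ex <- vapply(transcripts, function(t) nrow(t$exons), 0L)
  if (sum(n_ex) == 0L) {
    return(GenomicRanges::GRanges())
  }
  starts <- unlist(lapply(transcripts, function(t) t$exons[, 1L]))
  ends <- unlist(lapply(transcripts, function(t) t$exons[, 2L]))
  gr <- GenomicRanges::GRanges(
    seqnames = rep(vapply(transcripts, `[[`, "", "chrom"), n_ex),
    ranges = IRanges::IRanges(start = starts + 1, end = ends),
    strand = rep(vapply(transcripts, `[[`, "", "strand"), n_ex))
  gr$transcript_id <- rep(vapply(transcripts, `[[`, "", "transcript_id"), n_ex)
  gr$transcript_idx <- rep(seq_along(transcripts), n_ex)
  gr
}
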