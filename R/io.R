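#' Parse a GTF annotation into gene models
#'
#' Reads exon features from GTF text (Ensembl attribute dialect: `gene_id`,
#' `transcript_id`, optional `gene_biotype`), groups exons into transcripts
#' and transcripts into genes, and converts the 1-based closed GTF
#' coordinates to the package-internal 0-based half-open convention.
#'
#' @param x path to a GTF file, or a character vector of GTF lines.
#' @return list of [gene_model()] objects, sorted by gene id.
#' @export
parse_gtf <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad))
    stop("GTF format error: line ", bad[1L], " has fewer than 9 fields")
  feat <- vapply(fields, `[[`, "", 3L)
  keep <- which(feat == "exon")
  if (length(keep) == 0L) return(list())

  attr_of <- function(attrs, key, lineno) {
    m <- regmatches(attrs, regexec(paste0(key, "\\s+\"([^\"]*)\""), attrs))[[1L]]
    if (length(m) < 2L) return(NA_character_)
    m[2L]
  }
  rec <- lapply(keep, function(i) {
    f <- fields[[i]]
    attrs <- f[9L]
    tid <- attr_of(attrs, "transcript_id", i)
    if (is.na(tid))
      stop("GTF format error: missing transcript_id attribute on line ", i)
    gid <- attr_of(attrs, "gene_id", i)
    if (is.na(gid))
      stop("GTF format error: missing gene_id attribute on line ", i)
    bt <- attr_of(attrs, "gene_biotype", i)
    list(chrom = f[1L], start = as.numeric(f[4L]) - 1, end = as.numeric(f[5L]),
         strand = f[7L], gene_id = gid, transcript_id = tid, biotype = bt)
  })
  df <- data.frame(chrom = vapply(rec, `[[`, "", "chrom"),
                   start = vapply(rec, `[[`, 0, "start"),
                   end = vapply(rec, `[[`, 0, "end"),
                   strand = vapply(rec, `[[`, "", "strand"),
                   gene_id = vapply(rec, `[[`, "", "gene_id"),
                   transcript_id = vapply(rec, `[[`, "", "transcript_id"),
                   biotype = vapply(rec, `[[`, "", "biotype"),
                   stringsAsFactors = FALSE)

  genes <- lapply(split(df, df$gene_id), function(g) {
    txs <- lapply(split(g, g$transcript_id), function(tx) {
      transcript_model(tx$transcript_id[1L], tx$gene_id[1L], tx$chrom[1L],
                       tx$strand[1L], cbind(tx$start, tx$end))
    })
    txs <- txs[order(names(txs))]
    bt <- g$biotype[1L]
    biotype <- if (is.na(bt)) "other"
      else if (bt == "protein_coding") "protein_coding"
      else if (bt %in% c("lincRNA", "lncRNA", "noncoding", "antisense")) "noncoding"
      else "other"
    gene_model(g$gene_id[1L], biotype, txs)
  })
  genes[order(names(genes))]
}

#' Write gene models as GTF text
#'
#' Emits one exon line per exon with `gene_id`, `transcript_id` and
#' `gene_biotype` attributes, converting back to 1-based closed coordinates.
#' Output is deterministic: genes, transcripts and exons are sorted.
#'
#' @param genes list of [gene_model()] objects.
#' @param path optional file path; when `NULL` the lines are returned.
#' @return character vector of GTF lines (invisibly when written to a file).
#' @export
write_gtf <- function(genes, path = NULL) {
  genes <- genes[order(vapply(genes, `[[`, "", "gene_id"))]
  biotype_out <- c(protein_coding = "protein_coding", noncoding = "lincRNA",
                   other = "misc_RNA")
  lines <- unlist(lapply(genes, function(g) {
    txs <- g$transcripts[order(names(g$transcripts))]
    unlist(lapply(txs, function(t) {
      sprintf(paste0("%s\tlongtrx\texon\t%d\t%d\t.\t%s\t.\t",
                     "gene_id \"%s\"; transcript_id \"%s\"; gene_biotype \"%s\";"),
              t$chrom, t$exons[, 1L] + 1, t$exons[, 2L], t$strand,
              g$gene_id, t$transcript_id, biotype_out[[g$biotype]])
    }))
  }))
  if (is.null(lines)) lines <- character(0)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# Decode a CIGAR string into (query_span, ref_span, lead_clip, tail_clip).
cigar_spans <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  len <- as.numeric(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^\\d+", "", ops)
  qspan <- sum(len[op %in% c("M", "I", "=", "X")])
  rspan <- sum(len[op %in% c("M", "D", "N", "=", "X")])
  lead <- if (length(op) && op[1L] %in% c("S", "H")) len[1L] else 0
  tail <- if (length(op) > 1L && op[length(op)] %in% c("S", "H"))
    len[length(op)] else 0
  c(qspan = qspan, rspan = rspan, lead = lead, tail = tail)
}

#' Parse long-read alignments into chimeric alignment records
#'
#' All alignment lines of one query (primary plus supplementary/split lines)
#' are merged into a single [chimeric_alignment()]. For SAM input, query
#' intervals are reconstructed from soft/hard clipping, and coordinates of
#' reverse-strand lines are flipped back to the forward read orientation.
#' For PAF input the query interval columns are used directly. Unmapped
#' records yield a record with zero segments.
#'
#' @param x path to a file or a character vector of alignment lines.
#' @param dialect `"paf"` or `"sam"`.
#' @param drop_mapq0 drop segments with mapping quality 0 (default keeps
#'   them; they remain flagged via the per-segment `mapq` field).
#' @return list of [chimeric_alignment()] objects, one per query, in order
#'   of first appearance.
#' @export
parse_alignments <- function(x, dialect = c("paf", "sam"), drop_mapq0 = FALSE) {
  dialect <- match.arg(dialect)
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(lines)]
  if (dialect == "sam") lines <- lines[!grepl("^@", lines)]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)

  if (dialect == "paf") {
    recs <- lapply(fields, function(f) {
      if (length(f) < 12L) stop("PAF format error: fewer than 12 columns")
      list(qname = f[1L], qlen = as.numeric(f[2L]),
           seg = if (f[6L] == "*") NULL else
             aligned_segment(as.numeric(f[3L]), as.numeric(f[4L]), f[6L],
                             f[5L], as.numeric(f[8L]), as.numeric(f[9L]),
                             mapq = as.numeric(f[12L])))
    })
  } else {
    recs <- lapply(seq_along(fields), function(i) {
      f <- fields[[i]]
      if (length(f) < 11L)
        stop("SAM format error: line ", i, " has fewer than 11 fields")
      flag <- as.integer(f[2L])
      qname <- f[1L]
      if (bitwAnd(flag, 4L) > 0L || f[3L] == "*") {
        qlen <- if (f[10L] != "*") nchar(f[10L]) else NA_real_
        return(list(qname = qname, qlen = qlen, seg = NULL))
      }
      sp <- cigar_spans(f[6L])
      qlen <- sp[["lead"]] + sp[["qspan"]] + sp[["tail"]]
      qs <- sp[["lead"]]
      qe <- qs + sp[["qspan"]]
      if (bitwAnd(flag, 16L) > 0L) {
        strand <- "-"
        # SAM stores the reverse-complemented read: flip to forward-read coords
        tmp <- qs
        qs <- qlen - qe
        qe <- qlen - tmp
      } else strand <- "+"
      ts <- as.numeric(f[4L]) - 1
      list(qname = qname, qlen = qlen,
           seg = aligned_segment(qs, qe, f[3L], strand, ts, ts + sp[["rspan"]],
                                 mapq = as.numeric(f[5L])))
    })
  }

  qnames <- vapply(recs, `[[`, "", "qname")
  out <- list()
  for (qn in unique(qnames)) {
    rr <- recs[qnames == qn]
    qlens <- unique(stats::na.omit(vapply(rr, `[[`, 0, "qlen")))
    if (length(qlens) > 1L)
      stop("read '", qn, "': inconsistent query length across alignment lines (",
           paste(qlens, collapse = ", "), ")")
    segs <- Filter(Negate(is.null), lapply(rr, `[[`, "seg"))
    if (drop_mapq0)
      segs <- Filter(function(s) is.na(s$mapq) || s$mapq > 0, segs)
    out[[qn]] <- chimeric_alignment(qn, if (length(qlens)) qlens else 1, segs)
  }
  unname(out)
}

#' Write chimeric alignments as PAF text
#'
#' @param alignments list of [chimeric_alignment()] objects.
#' @param path optional output file.
#' @return character vector of PAF lines, sorted by query id then query start.
#' @export
write_paf <- function(alignments, path = NULL) {
  rows <- unlist(lapply(alignments, function(a) {
    if (length(a$segments) == 0L) return(NULL)
    vapply(a$segments, function(s) {
      span <- s$query_end - s$query_start
      sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
              a$query_id, a$query_length, s$query_start, s$query_end,
              s$strand, s$chrom, s$target_end + 1000000, s$target_start,
              s$target_end, span, span,
              ifelse(is.na(s$mapq), 60, s$mapq))
    }, "")
  }))
  if (is.null(rows)) rows <- character(0)
  rows <- sort(rows)
  if (!is.null(path)) {
    writeLines(rows, path)
    return(invisible(rows))
  }
  rows
}

#' Read a BED3+ file into a peak set
#'
#' @param path BED file (0-based half-open, as BED is defined).
#' @param name label for the peak set; defaults to the file name.
#' @return a [peak_set()].
#' @export
read_peaks_bed <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L)
    return(peak_set(name, data.frame(chrom = character(0), start = numeric(0),
                                     end = numeric(0))))
  f <- strsplit(lines, "\t", fixed = TRUE)
  peak_set(name, data.frame(chrom = vapply(f, `[[`, "", 1L),
                            start = as.numeric(vapply(f, `[[`, "", 2L)),
                            end = as.numeric(vapply(f, `[[`, "", 3L)),
                            stringsAsFactors = FALSE))
}

#' Write a peak set (or any interval frame) as BED3
#' @param peaks a [peak_set()] or data.frame with chrom/start/end.
#' @param path output file.
#' @export
write_bed <- function(peaks, path) {
  iv <- if (inherits(peaks, "PeakSet")) peaks$intervals else peaks
  iv <- iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d", iv$chrom, iv$start, iv$end), path)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of feature ids.
#' Values must be non-negative.
#'
#' @param path TSV file.
#' @return numeric matrix, features in rows, samples in columns.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "numeric"
  if (anyNA(m)) stop("expression matrix contains missing values")
  if (any(m < 0)) stop("expression matrix contains negative values")
  m
}

#' Write an expression matrix as TSV
#' @param m numeric matrix with feature rownames and sample colnames.
#' @param path output file.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a coding-potential call table
#'
#' One row per transcript, one column per predictor
#' (CNCI, PLEK, CPC, PfamScan), entries `"coding"` or `"noncoding"`.
#'
#' @param path TSV with a `transcript_id` column plus the four predictors.
#' @return data.frame with rownames = transcript ids.
#' @export
read_coding_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  predictors <- c("CNCI", "PLEK", "CPC", "PfamScan")
  missing <- setdiff(predictors, names(df))
  if (length(missing))
    stop("coding-call table is missing predictor column(s): ",
         paste(missing, collapse = ", "))
  rownames(df) <- df$transcript_id
  df[, predictors, drop = FALSE]
}

#' Write a data.frame as a deterministic TSV
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
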