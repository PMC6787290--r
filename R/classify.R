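#' Classify long-read transcripts against a reference annotation
#'
#' Each query transcript receives exactly one novelty category:
#' \describe{
#'   \item{known_isoform_known_gene}{its intron chain (see
#'     [intron_chain_key()]) matches an annotated transcript;}
#'   \item{novel_isoform_known_gene}{no chain match, but at least 1 bp of
#'     same-strand exonic overlap with an annotated gene;}
#'   \item{isoform_novel_gene}{no gene overlap; the representative transcript
#'     of a novel locus (queries clustered by single-linkage same-strand
#'     exonic overlap; the representative is the longest transcript by summed
#'     exon length, ties broken by lexicographic transcript id);}
#'   \item{novel_isoform_novel_gene}{a further transcript at a novel locus
#'     whose intron chain differs from the locus representative's.}
#' }
#' Queries whose only exonic overlap with annotation is on the opposite
#' strand are treated as novel-gene class and flagged `antisense`.
#'
#' @param transcripts list of query [transcript_model()] objects.
#' @param annotation list of [gene_model()] objects.
#' @return data.frame with columns `transcript_id`, `category`,
#'   `matched_gene_id` (annotated gene or `novel_locus_<chrom>_<k>` label)
#'   and `antisense`.
#' @export
classify_transcripts <- function(transcripts, annotation) {
  empty <- data.frame(transcript_id = character(0), category = character(0),
                      matched_gene_id = character(0), antisense = logical(0),
                      stringsAsFactors = FALSE)
  if (length(transcripts) == 0L) return(empty)
  qids <- vapply(transcripts, `[[`, "", "transcript_id")
  category <- rep(NA_character_, length(transcripts))
  matched <- rep(NA_character_, length(transcripts))
  antisense <- rep(FALSE, length(transcripts))

  ann_tx <- annotation_transcripts(annotation)
  ann_keys <- vapply(ann_tx, intron_chain_key, "")
  ann_gene_of_key <- vapply(ann_tx, `[[`, "", "gene_id")
  q_keys <- vapply(transcripts, intron_chain_key, "")

  # (1) known isoform: exact intron-chain match
  hit <- match(q_keys, ann_keys)
  known <- !is.na(hit)
  category[known] <- "known_isoform_known_gene"
  matched[known] <- ann_gene_of_key[hit[known]]

  # (2) novel isoform of a known gene: same-strand exonic overlap >= 1 bp
  ann_ex <- exons_granges(ann_tx)
  if (length(ann_ex))
    ann_ex$gene_id <- rep(vapply(ann_tx, `[[`, "", "gene_id"),
                          vapply(ann_tx, function(t) nrow(t$exons), 0L))
  todo <- which(!known)
  if (length(todo) && length(ann_ex)) {
    q_ex <- exons_granges(transcripts[todo])
    ov <- GenomicRanges::findOverlaps(q_ex, ann_ex, ignore.strand = FALSE)
    if (length(ov)) {
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(q_ex[S4Vectors::queryHits(ov)]),
        IRanges::ranges(ann_ex[S4Vectors::subjectHits(ov)])))
      odf <- data.frame(q = todo[q_ex$transcript_idx[S4Vectors::queryHits(ov)]],
                        gene = ann_ex$gene_id[S4Vectors::subjectHits(ov)],
                        w = w)
      agg <- stats::aggregate(w ~ q + gene, data = odf, FUN = sum)
      for (qi in unique(agg$q)) {
        sub <- agg[agg$q == qi, ]
        sub <- sub[order(-sub$w, sub$gene), ]
        category[qi] <- "novel_isoform_known_gene"
        matched[qi] <- sub$gene[1L]
      }
    }
    # antisense flag: exonic overlap on the opposite strand only
    left <- todo[is.na(category[todo])]
    if (length(left)) {
      q_ex2 <- exons_granges(transcripts[left])
      ov2 <- GenomicRanges::findOverlaps(q_ex2, ann_ex, ignore.strand = TRUE)
      antisense[unique(left[q_ex2$transcript_idx[S4Vectors::queryHits(ov2)]])] <- TRUE
    }
  }

  # (3) remaining queries: cluster into novel loci by single-linkage
  # same-strand exonic overlap
  rest <- which(is.na(category))
  if (length(rest)) {
    comp <- seq_along(rest)                      # union-find over rest
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    r_ex <- exons_granges(transcripts[rest])
    ov <- GenomicRanges::findOverlaps(r_ex, r_ex, ignore.strand = FALSE)
    qi <- r_ex$transcript_idx[S4Vectors::queryHits(ov)]
    si <- r_ex$transcript_idx[S4Vectors::subjectHits(ov)]
    for (k in seq_along(qi)) {
      a <- find(qi[k]); b <- find(si[k])
      if (a != b) comp[max(a, b)] <- min(a, b)
    }
    roots <- vapply(seq_along(rest), find, 0L)
    lens <- vapply(transcripts[rest],
                   function(t) sum(t$exons[, 2L] - t$exons[, 1L]), 0)
    locus_n <- 0L
    locus_counter <- new.env()
    for (r in sort(unique(roots))) {
      members <- which(roots == r)
      ord <- members[order(-lens[members], qids[rest][members])]
      rep_idx <- rest[ord[1L]]
      chrom <- transcripts[[rep_idx]]$chrom
      k <- get0(chrom, envir = locus_counter, ifnotfound = 0L) + 1L
      assign(chrom, k, envir = locus_counter)
      locus_id <- sprintf("novel_locus_%s_%d", chrom, k)
      rep_key <- q_keys[rep_idx]
      for (m in ord) {
        idx <- rest[m]
        category[idx] <- if (q_keys[idx] == rep_key)
          "isoform_novel_gene" else "novel_isoform_novel_gene"
        matched[idx] <- locus_id
      }
    }
  }

  data.frame(transcript_id = qids, category = category,
             matched_gene_id = matched, antisense = antisense,
             stringsAsFactors = FALSE)
}

#' Count novel transcripts shared among samples
#'
#' For every non-empty subset of samples, counts the isoform keys present in
#' exactly that subset. Counts over all subsets sum to the size of the union
#' of all keys.
#'
#' @param sets named list of character vectors (per-sample sets of novel
#'   transcript keys); at most 10 samples.
#' @return data.frame with columns `combination` (sample names joined by
#'   `"+"`), `n_samples` and `count`, one row per non-empty subset.
#' @export
sharing_counts <- function(sets) {
  stopifnot(length(sets) >= 1L, length(sets) <= 10L)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be a named list")
  samples <- names(sets)
  n <- length(samples)
  all_keys <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) all_keys %in% s,
                       logical(length(all_keys)))
  if (length(all_keys) == 1L) membership <- matrix(membership, nrow = 1L)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1L, , drop = FALSE]
  combo <- apply(subsets, 1L, function(m) paste(samples[as.logical(m)],
                                                collapse = "+"))
  count <- apply(subsets, 1L, function(m) {
    if (length(all_keys) == 0L) return(0L)
    sum(apply(membership, 1L, function(row) all(row == as.logical(m))))
  })
  out <- data.frame(combination = combo,
                    n_samples = rowSums(subsets),
                    count = as.integer(count),
                    stringsAsFactors = FALSE)
  out <- out[order(out$n_samples, out$combination), ]
  rownames(out) <- NULL
  out
}

#' Distance from each transcript's TSS to the nearest peak
#'
#' Distance is 0 when the TSS lies inside a peak interval, otherwise the
#' unsigned gap to the nearest peak boundary on the same chromosome.
#' Transcripts on chromosomes without any peak receive `Inf` and are
#' excluded from the summary fractions.
#'
#' @param transcripts list of [transcript_model()] objects.
#' @param peaks a [peak_set()].
#' @param breaks distance thresholds for the cumulative summary.
#' @return list with `records` (data.frame transcript_id / peak_set /
#'   distance) and `summary` (fraction of finite-distance TSSs within each
#'   threshold).
#' @export
tss_peak_distances <- function(transcripts, peaks,
                               breaks = c(1, 10, 100, 1000, 10000)) {
  stopifnot(inherits(peaks, "PeakSet"))
  tss <- vapply(transcripts, tss_of, 0)
  chrom <- vapply(transcripts, `[[`, "", "chrom")
  iv <- peaks$intervals
  dist <- vapply(seq_along(transcripts), function(i) {
    p <- iv[iv$chrom == chrom[i], , drop = FALSE]
    if (nrow(p) == 0L) return(Inf)
    # distance to the nearest covered base: 0 inside [start, end)
    min(pmax(pmax(p$start - tss[i], tss[i] - (p$end - 1)), 0))
  }, 0)
  records <- data.frame(
    transcript_id = vapply(transcripts, `[[`, "", "transcript_id"),
    peak_set = peaks$name, distance = dist, stringsAsFactors = FALSE)
  finite <- dist[is.finite(dist)]
  summary <- data.frame(
    threshold_bp = breaks,
    fraction_within = if (length(finite))
      vapply(breaks, function(b) mean(finite <= b), 0) else NA_real_)
  list(records = records, summary = summary)
}
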