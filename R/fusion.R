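#' Parameters for fusion-transcript detection
#'
#' The four detection criteria for a chimeric long read: (1) each mapped
#' locus covers at least `min_locus_query_fraction` of the query transcript;
#' (2) combined alignment coverage (union of query intervals) is at least
#' `min_combined_coverage`; (3) every pair of mapped loci lies on different
#' chromosomes or more than `min_locus_distance` bp apart; (4) at least
#' `min_spanning_reads` short reads span the fusion junction. A further
#' expression shortlist keeps fusions whose flanking read counts a and b
#' are each below `max_flank_to_spanning_ratio` times the spanning count s
#' (i.e. the fusion is expressed comparably to its parental genes).
#'
#' @param min_locus_query_fraction default 0.10.
#' @param min_combined_coverage default 0.99.
#' @param min_locus_distance bp, default 100000.
#' @param min_spanning_reads default 2.
#' @param max_flank_to_spanning_ratio default 2.0.
#' @return object of class `FusionParams`.
#' @export
fusion_params <- function(min_locus_query_fraction = 0.10,
                          min_combined_coverage = 0.99,
                          min_locus_distance = 1e5,
                          min_spanning_reads = 2,
                          max_flank_to_spanning_ratio = 2.0) {
  stopifnot(min_locus_query_fraction > 0, min_locus_query_fraction <= 1,
            min_combined_coverage > 0, min_combined_coverage <= 1,
            min_locus_distance > 0, min_spanning_reads >= 0,
            max_flank_to_spanning_ratio > 0)
  structure(list(min_locus_query_fraction = min_locus_query_fraction,
                 min_combined_coverage = min_combined_coverage,
                 min_locus_distance = min_locus_distance,
                 min_spanning_reads = min_spanning_reads,
                 max_flank_to_spanning_ratio = max_flank_to_spanning_ratio),
            class = "FusionParams")
}

# Union length of a set of half-open query intervals.
union_length <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  total <- 0; cur_s <- starts[1L]; cur_e <- ends[1L]
  for (k in seq_along(starts)[-1L]) {
    if (starts[k] <= cur_e) cur_e <- max(cur_e, ends[k])
    else { total <- total + (cur_e - cur_s); cur_s <- starts[k]; cur_e <- ends[k] }
  }
  total + (cur_e - cur_s)
}

#' Detect fusion-transcript candidates from chimeric alignments
#'
#' Applies the mapping criteria (1)-(3) of [fusion_params()] to every read
#' and records a per-read, per-criterion audit. A read is a candidate when
#' it has two or more aligned segments and passes all three criteria. Loci
#' of a candidate are ordered by their query interval, and the junction
#' between consecutive loci is recorded (read coordinate at the boundary
#' and the flanking genomic coordinates).
#'
#' @param alignments list of [chimeric_alignment()] objects.
#' @param params a [fusion_params()].
#' @return list with `audit` (data.frame: query_id, n_segments, multi_locus,
#'   pass_locus_coverage, pass_combined_coverage, pass_distance, candidate)
#'   and `candidates` (list of candidate records, each with `query_id`,
#'   `loci` data.frame and `junctions` data.frame).
#' @export
detect_candidates <- function(alignments, params = fusion_params()) {
  audit <- data.frame(
    query_id = vapply(alignments, `[[`, "", "query_id"),
    n_segments = vapply(alignments, function(a) length(a$segments), 0L),
    multi_locus = NA, pass_locus_coverage = NA, pass_combined_coverage = NA,
    pass_distance = NA, candidate = FALSE, stringsAsFactors = FALSE)
  candidates <- list()
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    nseg <- length(a$segments)
    audit$multi_locus[i] <- nseg >= 2L
    if (nseg < 2L) next
    qs <- vapply(a$segments, `[[`, 0, "query_start")
    qe <- vapply(a$segments, `[[`, 0, "query_end")
    frac <- (qe - qs) / a$query_length
    pass1 <- all(frac >= params$min_locus_query_fraction)
    pass2 <- union_length(qs, qe) / a$query_length >=
      params$min_combined_coverage
    chroms <- vapply(a$segments, `[[`, "", "chrom")
    ts <- vapply(a$segments, `[[`, 0, "target_start")
    te <- vapply(a$segments, `[[`, 0, "target_end")
    pass3 <- TRUE
    for (p in seq_len(nseg - 1L)) {
      for (q in (p + 1L):nseg) {
        if (chroms[p] != chroms[q]) next
        gap <- max(ts[q] - te[p], ts[p] - te[q], 0)
        if (gap <= params$min_locus_distance) { pass3 <- FALSE; break }
      }
      if (!pass3) break
    }
    audit$pass_locus_coverage[i] <- pass1
    audit$pass_combined_coverage[i] <- pass2
    audit$pass_distance[i] <- pass3
    ok <- pass1 && pass2 && pass3
    audit$candidate[i] <- ok
    if (!ok) next
    o <- order(qs)
    loci <- data.frame(chrom = chroms[o],
                       strand = vapply(a$segments, `[[`, "", "strand")[o],
                       target_start = ts[o], target_end = te[o],
                       query_start = qs[o], query_end = qe[o],
                       stringsAsFactors = FALSE)
    junctions <- data.frame(
      read_pos = (loci$query_end[-nrow(loci)] + loci$query_start[-1L]) / 2,
      left_chrom = loci$chrom[-nrow(loci)],
      left_genomic = ifelse(loci$strand[-nrow(loci)] == "+",
                            loci$target_end[-nrow(loci)],
                            loci$target_start[-nrow(loci)]),
      right_chrom = loci$chrom[-1L],
      right_genomic = ifelse(loci$strand[-1L] == "+",
                             loci$target_start[-1L], loci$target_end[-1L]))
    candidates[[length(candidates) + 1L]] <-
      list(query_id = a$query_id, query_length = a$query_length,
           loci = loci, junctions = junctions)
  }
  rownames(audit) <- NULL
  list(audit = audit, candidates = candidates)
}

#' Short-read support at fusion junctions
#'
#' Two input forms are accepted. A precomputed support table (data.frame
#' with columns `query_id`, `s`, `a`, `b`) is passed through verbatim for
#' the given candidates. Alternatively, short-read alignments onto the
#' fused transcript sequence (data.frame with columns `query_id`, `start`,
#' `end` in fused-transcript coordinates) are counted: `s` is the number of
#' reads covering the junction with at least `overhang` aligned bases on
#' both sides; `a` and `b` count reads overlapping the `flank_window` bp
#' immediately interior to the junction on each parent. Candidates without
#' a junction or without any support entry are marked unsupported
#' (`s = a = b = NA`).
#'
#' @param candidates `candidates` list from [detect_candidates()].
#' @param support support table or short-read alignment table (see above).
#' @param overhang minimum aligned bases on each side of the junction for a
#'   spanning read, default 8.
#' @param flank_window width of the flanking windows, default 100.
#' @return data.frame with columns `query_id`, `s`, `a`, `b`.
#' @export
count_junction_support <- function(candidates, support, overhang = 8,
                                   flank_window = 100) {
  qids <- vapply(candidates, `[[`, "", "query_id")
  if (all(c("s", "a", "b") %in% names(support))) {
    m <- match(qids, support$query_id)
    out <- data.frame(query_id = qids,
                      s = support$s[m], a = support$a[m], b = support$b[m],
                      stringsAsFactors = FALSE)
  } else if (all(c("start", "end") %in% names(support))) {
    out <- do.call(rbind, lapply(candidates, function(cand) {
      if (nrow(cand$junctions) == 0L)
        return(data.frame(query_id = cand$query_id, s = NA_real_,
                          a = NA_real_, b = NA_real_))
      j <- cand$junctions$read_pos[1L]
      r <- support[support$query_id == cand$query_id, , drop = FALSE]
      s <- sum(r$start <= j - overhang & r$end >= j + overhang)
      a <- sum(r$start < j & r$end > j - flank_window)
      b <- sum(r$start < j + flank_window & r$end > j)
      data.frame(query_id = cand$query_id, s = s, a = a, b = b,
                 stringsAsFactors = FALSE)
    }))
  } else {
    stop("'support' must have columns s/a/b or start/end")
  }
  rownames(out) <- NULL
  out
}

#' Apply junction support and expression filters to fusion candidates
#'
#' Tier 1 keeps candidates with at least `params$min_spanning_reads`
#' junction-spanning short reads (criterion 4). Tier 2, the shortlist for
#' experimental verification, additionally requires both flank-to-spanning
#' ratios a/s and b/s below `params$max_flank_to_spanning_ratio`; a
#' candidate with s = 0 fails tier 2 by definition.
#'
#' @param support data.frame from [count_junction_support()].
#' @param params a [fusion_params()].
#' @return the support data.frame with logical columns `tier1` and `tier2`
#'   added (NA support counts fail both tiers).
#' @export
apply_support_filters <- function(support, params = fusion_params()) {
  s <- support$s
  tier1 <- !is.na(s) & s >= params$min_spanning_reads
  tier2 <- tier1 & s > 0 &
    support$a / s < params$max_flank_to_spanning_ratio &
    support$b / s < params$max_flank_to_spanning_ratio
  tier2[is.na(tier2)] <- FALSE
  out <- support
  out$tier1 <- tier1
  out$tier2 <- tier2
  out
}

#' Assign parental genes to the loci of a fusion candidate
#'
#' Each locus is assigned the same-strand gene with maximal exonic overlap;
#' ties are broken by gene id. A locus overlapping no annotated gene's
#' exons is labelled `novel_locus:<chrom>:<start>`.
#'
#' @param candidate one candidate record from [detect_candidates()].
#' @param annotation list of [gene_model()] objects.
#' @return character vector of gene labels, one per locus (query order).
#' @export
assign_parental_genes <- function(candidate, annotation) {
  loci <- candidate$loci
  vapply(seq_len(nrow(loci)), function(i) {
    best_gene <- NA_character_; best_ov <- 0
    for (g in annotation) {
      if (g$chrom != loci$chrom[i] || g$strand != loci$strand[i]) next
      ov <- 0
      for (t in g$transcripts) {
        ov <- ov + sum(pmax(0, pmin(t$exons[, 2L], loci$target_end[i]) -
                              pmax(t$exons[, 1L], loci$target_start[i])))
      }
      if (ov > best_ov || (ov > 0 && ov == best_ov && g$gene_id < best_gene)) {
        best_gene <- g$gene_id; best_ov <- ov
      }
    }
    if (is.na(best_gene))
      sprintf("novel_locus:%s:%d", loci$chrom[i], as.integer(loci$target_start[i]))
    else best_gene
  }, "")
}

#' Match detected fusion gene pairs against a known-fusion database
#'
#' Database records are given as gene-symbol pairs; symbols are first
#' mapped to stable gene ids through `symbol_map`, then a detected pair
#' matches a database record iff both ids agree as an unordered pair.
#' Database records with unmappable symbols are skipped and reported.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` (stable ids of
#'   detected fusions).
#' @param db data.frame with columns `symbol_a`, `symbol_b`.
#' @param symbol_map data.frame with columns `symbol`, `gene_id`.
#' @return data.frame of detected pairs with a logical `in_database` column;
#'   skipped database records are attached as attribute `"unmapped"`.
#' @export
match_to_database <- function(pairs, db, symbol_map) {
  map <- stats::setNames(symbol_map$gene_id, symbol_map$symbol)
  ida <- unname(map[db$symbol_a]); idb <- unname(map[db$symbol_b])
  unmapped <- is.na(ida) | is.na(idb)
  if (any(unmapped))
    warning(sum(unmapped), " database record(s) skipped: unmapped symbol(s) ",
            paste(unique(c(db$symbol_a[unmapped][is.na(ida[unmapped])],
                           db$symbol_b[unmapped][is.na(idb[unmapped])])),
                  collapse = ", "))
  db_keys <- unique(paste(pmin(ida[!unmapped], idb[!unmapped]),
                          pmax(ida[!unmapped], idb[!unmapped]), sep = "|"))
  keys <- paste(pmin(pairs$gene_a, pairs$gene_b),
                pmax(pairs$gene_a, pairs$gene_b), sep = "|")
  out <- pairs
  out$in_database <- keys %in% db_keys
  attr(out, "unmapped") <- db[unmapped, , drop = FALSE]
  out
}
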