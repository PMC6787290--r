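# Independent brute-force oracles used to validate the package's optimised
# implementations on small inputs. These are written as direct, naive
# transcriptions of the definitions and share no code with the package.

# O(n*m) nearest-peak scan: distance from a single position to the nearest
# covered base of any interval on the same chromosome.
oracle_tss_distance <- function(pos, chrom, intervals) {
  best <- Inf
  for (k in seq_len(nrow(intervals))) {
    if (intervals$chrom[k] != chrom) next
    s <- intervals$start[k]; e <- intervals$end[k]
    d <- if (pos >= s && pos < e) 0 else min(abs(pos - s), abs(pos - (e - 1)))
    best <- min(best, d)
  }
  best
}

# Exact subset-membership enumeration for sharing counts.
oracle_sharing <- function(sets) {
  samples <- names(sets)
  keys <- unique(unlist(sets))
  out <- list()
  for (key in keys) {
    members <- samples[vapply(samples, function(s) key %in% sets[[s]], TRUE)]
    combo <- paste(members, collapse = "+")
    out[[combo]] <- (if (is.null(out[[combo]])) 0L else out[[combo]]) + 1L
  }
  out
}

# Direct per-read evaluation of the three mapping criteria for fusion
# candidacy. Combined coverage is measured by marking covered read bases.
oracle_fusion_candidate <- function(alignment, min_frac = 0.10,
                                    min_combined = 0.99, min_dist = 1e5) {
  segs <- alignment$segments
  if (length(segs) < 2L) return(FALSE)
  L <- alignment$query_length
  covered <- logical(L)
  for (s in segs) {
    if ((s$query_end - s$query_start) / L < min_frac) return(FALSE)
    covered[(s$query_start + 1):s$query_end] <- TRUE
  }
  if (sum(covered) / L < min_combined) return(FALSE)
  for (i in seq_along(segs)) {
    for (j in seq_along(segs)) {
      if (i >= j) next
      a <- segs[[i]]; b <- segs[[j]]
      if (a$chrom != b$chrom) next
      gap <- max(b$target_start - a$target_end, a$target_start - b$target_end, 0)
      if (gap <= min_dist) return(FALSE)
    }
  }
  TRUE
}

# Literal evaluation of the summed Jaccard divergence.
oracle_divergence <- function(normal, cancers, gene) {
  b <- normal[[gene]]
  if (is.null(b)) b <- character(0)
  total <- 0
  for (cat in cancers) {
    a <- cat[[gene]]
    if (is.null(a)) a <- character(0)
    u <- unique(c(a, b))
    if (length(u) > 0)
      total <- total + (1 - sum(a %in% b & !duplicated(a)) / length(u))
  }
  total
}

# Exhaustive pairwise enumeration of local splicing events, coded naively
# from the event definitions. Returns a sorted character vector of
# "type coordinates" identifiers for comparison with enumerate_as_events().
oracle_as_events <- function(gene) {
  txs <- gene$transcripts
  strand <- gene$strand
  found <- character(0)
  note <- function(type, ...) {
    found <<- c(found, paste(type, paste(c(...), collapse = ":")))
  }
  intr <- function(ex) {
    if (nrow(ex) < 2L) return(NULL)
    cbind(ex[-nrow(ex), 2L], ex[-1L, 1L])
  }
  overlap <- function(a, b) a[1L] < b[2L] && b[1L] < a[2L]
  for (t1 in txs) for (t2 in txs) {
    if (t1$transcript_id == t2$transcript_id) next
    e1 <- t1$exons; e2 <- t2$exons
    i1 <- intr(e1); i2 <- intr(e2)
    # SE: internal exon of t1, flanking outer bounds form one intron of t2
    if (nrow(e1) >= 3L && !is.null(i2)) {
      for (k in 2:(nrow(e1) - 1L)) {
        for (q in seq_len(nrow(i2))) {
          if (i2[q, 1L] == e1[k - 1L, 2L] && i2[q, 2L] == e1[k + 1L, 1L])
            note("SE", e1[k - 1L, 2L], e1[k, 1L], e1[k, 2L], e1[k + 1L, 1L])
        }
      }
    }
    # RI: intron of t1 inside an exon of t2 with shared outer exon bounds
    if (!is.null(i1)) {
      for (k in seq_len(nrow(i1))) {
        for (q in seq_len(nrow(e2))) {
          if (e2[q, 1L] == e1[k, 1L] && e2[q, 2L] == e1[k + 1L, 2L])
            note("RI", e1[k, 1L], e1[k, 2L], e1[k + 1L, 1L], e1[k + 1L, 2L])
        }
      }
    }
    # A5/A3: introns sharing one boundary; differing-side exons overlap
    if (!is.null(i1) && !is.null(i2)) {
      for (k in seq_len(nrow(i1))) for (q in seq_len(nrow(i2))) {
        if (i1[k, 2L] == i2[q, 2L] && i1[k, 1L] != i2[q, 1L]) {
          d1 <- e1[e1[, 2L] == i1[k, 1L], ][1:2]
          d2 <- e2[e2[, 2L] == i2[q, 1L], ][1:2]
          if (overlap(d1, d2))
            note(if (strand == "+") "A5" else "A3",
                 min(i1[k, 1L], i2[q, 1L]), max(i1[k, 1L], i2[q, 1L]),
                 i1[k, 2L])
        }
        if (i1[k, 1L] == i2[q, 1L] && i1[k, 2L] != i2[q, 2L]) {
          a1 <- e1[e1[, 1L] == i1[k, 2L], ][1:2]
          a2 <- e2[e2[, 1L] == i2[q, 2L], ][1:2]
          if (overlap(a1, a2))
            note(if (strand == "+") "A3" else "A5",
                 i1[k, 1L], min(i1[k, 2L], i2[q, 2L]),
                 max(i1[k, 2L], i2[q, 2L]))
        }
      }
    }
    # MXE: mutually absent internal exons, non-overlapping, shared flanks
    if (nrow(e1) >= 3L && nrow(e2) >= 3L) {
      in_tx <- function(ex, row)
        any(ex[, 1L] == row[1L] & ex[, 2L] == row[2L])
      for (k in 2:(nrow(e1) - 1L)) for (q in 2:(nrow(e2) - 1L)) {
        A <- e1[k, 1:2]; B <- e2[q, 1:2]
        if (in_tx(e2, A) || in_tx(e1, B) || overlap(A, B)) next
        if (e1[k - 1L, 2L] == e2[q - 1L, 2L] &&
            e1[k + 1L, 1L] == e2[q + 1L, 1L]) {
          lo <- if (A[1L] < B[1L]) A else B
          hi <- if (A[1L] < B[1L]) B else A
          note("MXE", e1[k - 1L, 2L], lo[1L], lo[2L], hi[1L], hi[2L],
               e1[k + 1L, 1L])
        }
      }
    }
    # AF/AL: distinct non-overlapping terminal exons, shared inner boundary
    if (!is.null(i1) && !is.null(i2)) {
      f1 <- e1[1L, 1:2]; f2 <- e2[1L, 1:2]
      if (i1[1L, 2L] == i2[1L, 2L] && !overlap(f1, f2) &&
          !(f1[1L] == f2[1L] && f1[2L] == f2[2L])) {
        lo <- if (f1[1L] < f2[1L]) f1 else f2
        hi <- if (f1[1L] < f2[1L]) f2 else f1
        note(if (strand == "+") "AF" else "AL",
             lo[1L], lo[2L], hi[1L], hi[2L], i1[1L, 2L])
      }
      l1 <- e1[nrow(e1), 1:2]; l2 <- e2[nrow(e2), 1:2]
      if (i1[nrow(i1), 1L] == i2[nrow(i2), 1L] && !overlap(l1, l2) &&
          !(l1[1L] == l2[1L] && l1[2L] == l2[2L])) {
        lo <- if (l1[1L] < l2[1L]) l1 else l2
        hi <- if (l1[1L] < l2[1L]) l2 else l1
        note(if (strand == "+") "AL" else "AF",
             i1[nrow(i1), 1L], lo[1L], lo[2L], hi[1L], hi[2L])
      }
    }
  }
  sort(unique(found))
}

# Canonical form of the package's event table for oracle comparison.
event_signatures <- function(events) {
  sig <- vapply(seq_len(nrow(events)), function(i) {
    coords <- sub("^[A-Z0-9]+:[^:]+:[+-]:", "", events$event_id[i])
    paste(events$event_type[i], coords)
  }, "")
  sort(sig)
}

# Small two-transcript gene used across tests.
make_gene <- function(gene_id, exon_sets, strand = "+", chrom = "chr1",
                      biotype = "protein_coding") {
  txs <- lapply(seq_along(exon_sets), function(i)
    transcript_model(sprintf("%s.%d", gene_id, i), gene_id, chrom, strand,
                     exon_sets[[i]]))
  gene_model(gene_id, biotype, txs)
}
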