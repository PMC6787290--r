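#' Enumerate local alternative splicing events of a gene
#'
#' Compares all transcript pairs of a gene and reports the local events of
#' the seven standard types, deduplicated by defining coordinates:
#' \describe{
#'   \item{SE}{skipped exon: an internal exon of one transcript whose two
#'     flanking introns' outer boundaries form a single intron of another
#'     transcript;}
#'   \item{RI}{retained intron: one transcript's intron fully contained in
#'     another transcript's exon with both outer exon boundaries shared;}
#'   \item{A5/A3}{alternative 5'/3' splice site: two introns sharing one
#'     boundary and differing at the other, with the exons flanking the
#'     differing boundary overlapping (labels assigned strand-aware: the
#'     donor side is 5');}
#'   \item{MXE}{mutually exclusive exons: two non-overlapping internal
#'     exons, each absent from the other transcript, sharing both outer
#'     flanking intron boundaries;}
#'   \item{AF/AL}{alternative first/last exon: distinct, non-overlapping
#'     terminal exons spliced to a shared internal boundary (first/last
#'     taken strand-aware).}
#' }
#'
#' @param gene a [gene_model()]; genes with fewer than 2 transcripts yield
#'   no events.
#' @return data.frame with columns `gene_id`, `event_type`, `event_id`
#'   (type plus defining coordinates), `inclusion`, `exclusion`
#'   (comma-separated transcript id sets).
#' @export
enumerate_as_events <- function(gene) {
  empty <- data.frame(gene_id = character(0), event_type = character(0),
                      event_id = character(0), inclusion = character(0),
                      exclusion = character(0), stringsAsFactors = FALSE)
  txs <- gene$transcripts
  if (length(txs) < 2L) return(empty)
  strand <- gene$strand
  chrom <- gene$chrom
  events <- new.env(parent = emptyenv())

  add_event <- function(type, coords, incl, excl) {
    id <- paste0(type, ":", chrom, ":", strand, ":",
                 paste(coords, collapse = ":"))
    e <- get0(id, envir = events)
    if (is.null(e)) e <- list(type = type, incl = character(0),
                              excl = character(0))
    e$incl <- union(e$incl, incl)
    e$excl <- union(e$excl, excl)
    assign(id, e, envir = events)
  }
  exon_key <- function(ex) paste(ex[1L], ex[2L], sep = "-")
  has_intron <- function(t, d, a) {
    ii <- introns_of(t)
    any(ii[, 1L] == d & ii[, 2L] == a)
  }

  for (i in seq_along(txs)) {
    for (j in seq_along(txs)) {
      if (i == j) next
      t1 <- txs[[i]]; t2 <- txs[[j]]
      id1 <- t1$transcript_id; id2 <- t2$transcript_id
      ex1 <- t1$exons; ex2 <- t2$exons
      in1 <- introns_of(t1); in2 <- introns_of(t2)
      n1 <- nrow(ex1); n2 <- nrow(ex2)

      # SE: internal exon of t1 skipped by an intron of t2
      if (n1 >= 3L) {
        for (k in 2:(n1 - 1L)) {
          d <- ex1[k - 1L, 2L]; a <- ex1[k + 1L, 1L]
          if (has_intron(t2, d, a))
            add_event("SE", c(d, ex1[k, 1L], ex1[k, 2L], a), id1, id2)
        }
      }

      # RI: intron of t1 retained inside an exon of t2 with shared outer bounds
      if (n1 >= 2L) {
        for (k in seq_len(n1 - 1L)) {
          s1 <- ex1[k, 1L]; e1 <- ex1[k, 2L]
          s2 <- ex1[k + 1L, 1L]; e2 <- ex1[k + 1L, 2L]
          if (any(ex2[, 1L] == s1 & ex2[, 2L] == e2))
            add_event("RI", c(s1, e1, s2, e2), id2, id1)
        }
      }

      # A5/A3: introns sharing exactly one boundary, flanking exons overlap
      if (nrow(in1) && nrow(in2)) {
        for (k in seq_len(nrow(in1))) {
          d1 <- in1[k, 1L]; a1 <- in1[k, 2L]
          # shared acceptor, differing donor (left boundary)
          m <- which(in2[, 2L] == a1 & in2[, 1L] != d1)
          for (q in m) {
            d2 <- in2[q, 1L]
            de1 <- ex1[ex1[, 2L] == d1, , drop = FALSE][1L, ]
            de2 <- ex2[ex2[, 2L] == d2, , drop = FALSE][1L, ]
            if (de1[1L] < de2[2L] && de2[1L] < de1[2L]) {
              type <- if (strand == "+") "A5" else "A3"
              incl_first <- d1 > d2   # longer exon (shorter intron) = inclusion
              add_event(type, c(min(d1, d2), max(d1, d2), a1),
                        if (incl_first) id1 else id2,
                        if (incl_first) id2 else id1)
            }
          }
          # shared donor, differing acceptor (right boundary)
          m <- which(in2[, 1L] == d1 & in2[, 2L] != a1)
          for (q in m) {
            a2 <- in2[q, 2L]
            ae1 <- ex1[ex1[, 1L] == a1, , drop = FALSE][1L, ]
            ae2 <- ex2[ex2[, 1L] == a2, , drop = FALSE][1L, ]
            if (ae1[1L] < ae2[2L] && ae2[1L] < ae1[2L]) {
              type <- if (strand == "+") "A3" else "A5"
              incl_first <- a1 < a2
              add_event(type, c(d1, min(a1, a2), max(a1, a2)),
                        if (incl_first) id1 else id2,
                        if (incl_first) id2 else id1)
            }
          }
        }
      }

      # MXE: internal exons of t1 and t2, mutually absent, non-overlapping,
      # sharing both outer flanking boundaries
      if (n1 >= 3L && n2 >= 3L) {
        ex2_keys <- apply(ex2, 1L, exon_key)
        ex1_keys <- apply(ex1, 1L, exon_key)
        for (k in 2:(n1 - 1L)) {
          e_a <- ex1[k, ]
          if (exon_key(e_a) %in% ex2_keys) next
          for (q in 2:(n2 - 1L)) {
            e_b <- ex2[q, ]
            if (exon_key(e_b) %in% ex1_keys) next
            if (e_a[1L] < e_b[2L] && e_b[1L] < e_a[2L]) next  # overlap
            if (ex1[k - 1L, 2L] == ex2[q - 1L, 2L] &&
                ex1[k + 1L, 1L] == ex2[q + 1L, 1L]) {
              left_first <- e_a[1L] < e_b[1L]
              lo <- if (left_first) e_a else e_b
              hi <- if (left_first) e_b else e_a
              add_event("MXE", c(ex1[k - 1L, 2L], lo[1L], lo[2L],
                                 hi[1L], hi[2L], ex1[k + 1L, 1L]),
                        if (left_first) id1 else id2,
                        if (left_first) id2 else id1)
            }
          }
        }
      }

      # AF/AL: distinct non-overlapping terminal exons spliced to a shared
      # internal boundary; first/last assigned strand-aware
      if (n1 >= 2L && n2 >= 2L && i < j) {
        # left end of the gene: first exon on +, last exon on -
        f1 <- ex1[1L, ]; f2 <- ex2[1L, ]
        if (in1[1L, 2L] == in2[1L, 2L] &&
            !(f1[1L] == f2[1L] && f1[2L] == f2[2L]) &&
            !(f1[1L] < f2[2L] && f2[1L] < f1[2L])) {
          type <- if (strand == "+") "AF" else "AL"
          lo <- if (f1[1L] < f2[1L]) f1 else f2
          hi <- if (f1[1L] < f2[1L]) f2 else f1
          # inclusion = the 5'-most form for AF, 3'-most for AL
          first_is_lo <- f1[1L] < f2[1L]
          add_event(type, c(lo[1L], lo[2L], hi[1L], hi[2L], in1[1L, 2L]),
                    if (first_is_lo) id1 else id2,
                    if (first_is_lo) id2 else id1)
        }
        # right end of the gene: last exon on +, first exon on -
        l1 <- ex1[n1, ]; l2 <- ex2[n2, ]
        if (in1[nrow(in1), 1L] == in2[nrow(in2), 1L] &&
            !(l1[1L] == l2[1L] && l1[2L] == l2[2L]) &&
            !(l1[1L] < l2[2L] && l2[1L] < l1[2L])) {
          type <- if (strand == "+") "AL" else "AF"
          lo <- if (l1[1L] < l2[1L]) l1 else l2
          hi <- if (l1[1L] < l2[1L]) l2 else l1
          first_is_lo <- l1[1L] < l2[1L]
          add_event(type, c(in1[nrow(in1), 1L], lo[1L], lo[2L],
                            hi[1L], hi[2L]),
                    if (first_is_lo) id1 else id2,
                    if (first_is_lo) id2 else id1)
        }
      }
    }
  }

  ids <- sort(ls(events))
  if (length(ids) == 0L) return(empty)
  rows <- lapply(ids, function(id) {
    e <- get(id, envir = events)
    incl <- sort(e$incl)
    excl <- sort(e$excl)
    if (length(intersect(incl, excl)))
      return(NULL)  # degenerate: a transcript supports both forms
    data.frame(gene_id = gene$gene_id, event_type = e$type, event_id = id,
               inclusion = paste(incl, collapse = ","),
               exclusion = paste(excl, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enumerate alternative splicing events for a whole annotation
#'
#' @param genes list of [gene_model()] objects.
#' @return row-bound data.frame of [enumerate_as_events()] results.
#' @export
enumerate_as_events_all <- function(genes) {
  out <- do.call(rbind, lapply(genes, enumerate_as_events))
  if (is.null(out))
    out <- data.frame(gene_id = character(0), event_type = character(0),
                      event_id = character(0), inclusion = character(0),
                      exclusion = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Event-type proportions per sample with a chi-squared homogeneity test
#'
#' Builds the sample-by-event-type contingency table of raw event counts,
#' the per-sample percentage table (each row sums to 100) and Pearson's
#' chi-squared test of homogeneity on the raw counts (no continuity
#' correction, df = (rows - 1)(cols - 1)).
#'
#' @param events_by_sample named list; each element either the data.frame
#'   returned by [enumerate_as_events_all()] or a named count vector over
#'   event types.
#' @return list with `counts` (matrix), `percentages` (matrix), `statistic`,
#'   `df`, `p.value`. Samples with zero events are excluded with a warning.
#' @export
event_type_proportions <- function(events_by_sample) {
  types <- c("SE", "MXE", "A5", "A3", "AF", "AL", "RI")
  stopifnot(length(events_by_sample) >= 2L,
            !is.null(names(events_by_sample)))
  counts <- t(vapply(events_by_sample, function(e) {
    if (is.data.frame(e)) {
      tab <- table(factor(e$event_type, levels = types))
      as.numeric(tab)
    } else {
      v <- stats::setNames(numeric(length(types)), types)
      v[names(e)] <- e
      as.numeric(v)
    }
  }, numeric(length(types))))
  colnames(counts) <- types
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    warning("sample(s) with zero events excluded: ",
            paste(rownames(counts)[zero], collapse = ", "))
    counts <- counts[!zero, , drop = FALSE]
  }
  if (nrow(counts) < 2L)
    stop("need at least 2 samples with events for the proportion test")
  percentages <- sweep(counts, 1L, rowSums(counts), "/") * 100
  used <- counts[, colSums(counts) > 0, drop = FALSE]
  if (all(apply(used, 2L, function(col) length(unique(col)) == 1L)) &&
      length(unique(rowSums(used))) == 1L) {
    # identical count vectors: chi-squared is exactly 0
    stat <- 0; df <- (nrow(used) - 1L) * (ncol(used) - 1L); p <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(used, correct = FALSE))
    stat <- unname(ct$statistic); df <- unname(ct$parameter); p <- ct$p.value
  }
  list(counts = counts, percentages = percentages,
       statistic = stat, df = df, p.value = p)
}

#' Build an isoform catalog from transcript models
#'
#' @param transcripts list of [transcript_model()] objects with `gene_id`
#'   set.
#' @return named list mapping gene id to the set (character vector) of
#'   isoform identity keys observed for that gene.
#' @export
isoform_catalog <- function(transcripts) {
  gid <- vapply(transcripts, `[[`, "", "gene_id")
  keys <- vapply(transcripts, intron_chain_key, "")
  lapply(split(keys, gid), unique)
}

#' Isoform-usage divergence score between cancer and normal catalogs
#'
#' For gene j with isoform set b in the normal sample and set a_i in cancer
#' sample i, the divergence is the summed Jaccard distance
#' \deqn{D_j = \sum_i (1 - |a_i \cap b| / |a_i \cup b|)}
#' over all cancer samples. A comparison in which the gene is absent from
#' both samples contributes 0. Each term lies in [0, 1], so
#' 0 <= D <= number of cancer samples; genes with higher D are more
#' diversely spliced relative to the normal sample.
#'
#' @param normal isoform catalog of the normal sample (named list,
#'   gene id -> character vector of isoform keys).
#' @param cancers list of isoform catalogs, one per cancer sample.
#' @return data.frame with columns `gene_id`, `D`, `n_comparisons`, sorted
#'   by decreasing D then gene id.
#' @export
divergence_score <- function(normal, cancers) {
  stopifnot(length(cancers) >= 1L)
  genes <- sort(unique(c(names(normal),
                         unlist(lapply(cancers, names), use.names = FALSE))))
  D <- vapply(genes, function(g) {
    b <- normal[[g]]
    if (is.null(b)) b <- character(0)
    sum(vapply(cancers, function(cat) {
      a <- cat[[g]]
      if (is.null(a)) a <- character(0)
      u <- union(a, b)
      if (length(u) == 0L) return(0)
      1 - length(intersect(a, b)) / length(u)
    }, 0))
  }, 0)
  out <- data.frame(gene_id = genes, D = unname(D),
                    n_comparisons = length(cancers),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$D, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Top diversely spliced genes
#'
#' @param scores data.frame from [divergence_score()].
#' @param n number of genes to return (descending D, ties broken by gene
#'   id). `top_fraction` may be given instead.
#' @param top_fraction fraction of genes to return.
#' @return character vector of gene ids.
#' @export
rank_spliced_genes <- function(scores, n = NULL, top_fraction = NULL) {
  stopifnot(nrow(scores) > 0L, xor(is.null(n), is.null(top_fraction)))
  if (is.null(n)) n <- ceiling(top_fraction * nrow(scores))
  if (n > nrow(scores)) {
    warning("requested ", n, " genes but only ", nrow(scores),
            " have scores; returning all")
    n <- nrow(scores)
  }
  ord <- scores[order(-scores$D, scores$gene_id), ]
  utils::head(ord$gene_id, n)
}
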