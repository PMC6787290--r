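#' Configuration for the synthetic-data generators
#'
#' The defaults emulate the study design the package targets: five samples
#' (one normal-like line and four cancer lines), protein-coding genes with
#' planted local splicing events of all seven types, lincRNA genes placed
#' near or far from coding partners for target prediction, and a chimeric
#' long-read set with planted fusions that satisfy all four detection
#' criteria alongside reads that each violate exactly one of them.
#'
#' @param seed integer seed (mandatory; every generator is a pure function
#'   of the configuration including the seed).
#' @param n_genes number of protein-coding genes.
#' @param n_lincrna_genes number of lincRNA genes.
#' @param genes_per_chrom coding genes placed per synthetic chromosome.
#' @param chrom_length length of each synthetic chromosome in bp.
#' @param as_event_fraction fraction of coding genes given one planted
#'   alternative-splicing event (types cycle through SE, MXE, A5, A3, AF,
#'   AL, RI); the rest are single-transcript genes.
#' @param n_exons_range inclusive range of exon counts per coding
#'   transcript (minimum 4, so every event type has room).
#' @param n_samples number of samples (first is the normal-like one).
#' @param n_expression_samples samples in the expression matrix used for
#'   target prediction (correlation needs more samples than the five-line
#'   design to make the dual r/p thresholds jointly satisfiable).
#' @param n_true_fusions,n_fails_coverage,n_fails_combined,n_fails_distance,n_fails_support
#'   planted chimeric reads per fusion class.
#' @param n_non_fusion ordinary single-locus reads.
#' @param read_length length of synthetic long reads (bp).
#' @param n_target_pairs planted co-expressed, co-located lincRNA-gene pairs.
#' @param n_far_decoys correlated pairs planted beyond the location window.
#' @param n_near_decoys co-located pairs planted without correlation.
#' @param expression_sigma log-normal noise sd on expression values.
#' @param n_specific,n_in_reference,n_normal_only,n_ubiquitous planted
#'   lincRNA presence classes for the cancer-specific set logic.
#' @param n_ccs circular-consensus reads per sample for the QC metadata
#'   table.
#' @return object of class `SimulationConfig`.
#' @export
sim_config <- function(seed,
                       n_genes = 60,
                       n_lincrna_genes = 40,
                       genes_per_chrom = 10,
                       chrom_length = 25e6,
                       as_event_fraction = 0.5,
                       n_exons_range = c(4, 7),
                       n_samples = 5,
                       n_expression_samples = 12,
                       n_true_fusions = 20,
                       n_fails_coverage = 8,
                       n_fails_combined = 8,
                       n_fails_distance = 8,
                       n_fails_support = 8,
                       n_non_fusion = 148,
                       read_length = 2000,
                       n_target_pairs = 6,
                       n_far_decoys = 4,
                       n_near_decoys = 4,
                       expression_sigma = 0.25,
                       n_specific = 10,
                       n_in_reference = 5,
                       n_normal_only = 5,
                       n_ubiquitous = 5,
                       n_ccs = 400) {
  if (missing(seed) || !is.numeric(seed))
    stop("'seed' is mandatory in sim_config()")
  cfg <- as.list(environment())
  counts <- unlist(cfg[setdiff(names(cfg), "seed")])
  if (any(counts < 0)) stop("all configuration counts must be >= 0")
  if (cfg$n_samples < 2) stop("need at least one normal and one cancer sample")
  if (length(cfg$n_exons_range) != 2L || cfg$n_exons_range[1L] < 4)
    stop("n_exons_range must be a range with a minimum of at least 4")
  cfg$sample_names <- c("normal", paste0("cancer", seq_len(n_samples - 1L)))
  structure(cfg, class = "SimulationConfig")
}

# Draw a multi-exon structure: returns exon matrix with n exons.
random_exons <- function(start, n_exons, exon_range = c(120, 300),
                         intron_range = c(400, 1200)) {
  lens <- round(stats::runif(n_exons, exon_range[1L], exon_range[2L]))
  gaps <- round(stats::runif(n_exons - 1L, intron_range[1L], intron_range[2L]))
  starts <- start + cumsum(c(0, lens[-n_exons] + gaps))
  cbind(start = starts, end = starts + lens)
}

# Derive the second transcript of a gene so that exactly one local event of
# the requested type is enumerable from the pair. `side` geometry is chosen
# strand-aware so that the planted label matches the enumerator's convention.
plant_event_variant <- function(exons, type, strand) {
  n <- nrow(exons)
  boundary_side <- function(type) {
    # A5 alters the donor (left boundary on +, right on -); A3 the acceptor
    if (type == "A5") {
      if (strand == "+") "left" else "right"
    } else {
      if (strand == "+") "right" else "left"
    }
  }
  if (type == "SE") {
    k <- ceiling(n / 2)
    exons[-k, , drop = FALSE]
  } else if (type == "RI") {
    k <- ceiling(n / 2) - 1L
    merged <- exons
    merged[k, 2L] <- merged[k + 1L, 2L]
    merged[-(k + 1L), , drop = FALSE]
  } else if (type %in% c("A5", "A3")) {
    k <- ceiling(n / 2)   # intron k = between exon k and exon k+1
    v <- exons
    gap <- exons[k + 1L, 1L] - exons[k, 2L]
    shift <- round(gap / 3)
    if (boundary_side(type) == "left") v[k, 2L] <- v[k, 2L] + shift
    else v[k + 1L, 1L] <- v[k + 1L, 1L] - shift
    v
  } else if (type == "MXE") {
    k <- ceiling(n / 2)
    v <- exons
    gap_after <- exons[k + 1L, 1L] - exons[k, 2L]
    len <- exons[k, 2L] - exons[k, 1L]
    offset <- min(round(gap_after / 2), len + 60)
    v[k, ] <- c(exons[k, 1L] + len + round(offset / 2),
                exons[k, 2L] + len + round(offset / 2))
    if (v[k, 2L] >= v[k + 1L, 1L]) v[k, ] <- v[k, ] - (v[k, 2L] - v[k + 1L, 1L] + 50)
    v
  } else if (type == "AF" || type == "AL") {
    left_end <- (type == "AF") == (strand == "+")
    v <- exons
    if (left_end) {
      gap <- exons[2L, 1L] - exons[1L, 2L]
      len <- round((exons[1L, 2L] - exons[1L, 1L]) / 2)
      new_start <- exons[1L, 2L] + round(gap / 4)
      v[1L, ] <- c(new_start, new_start + len)
    } else {
      gap <- exons[n, 1L] - exons[n - 1L, 2L]
      len <- round((exons[n, 2L] - exons[n, 1L]) / 2)
      new_end <- exons[n, 1L] - round(gap / 4)
      v[n, ] <- c(new_end - len, new_end)
    }
    v
  } else stop("unknown event type: ", type)
}

#' Simulate a reference annotation with planted splicing events
#'
#' Coding genes are placed without overlap along synthetic chromosomes with
#' large intergenic gaps (every pair of genes is more than 100 kb apart, as
#' fusion-distance tests require). A configurable fraction of coding genes
#' carries exactly one planted alternative-splicing event; the event types
#' cycle through the seven categories. lincRNA genes are interleaved after
#' coding genes, some within the 100-kb co-location window of their coding
#' neighbour ("near"), some beyond it ("far"), the rest generic.
#'
#' @param cfg a [sim_config()].
#' @return list with `genes` (list of [gene_model()]), `chrom_lengths`
#'   (named vector) and `truth` (list with `planted_events` and
#'   `linc_placement` data.frames, plus the seed).
#' @export
simulate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  types <- c("SE", "MXE", "A5", "A3", "AF", "AL", "RI")
  n_as <- round(cfg$as_event_fraction * cfg$n_genes)
  as_types <- if (n_as > 0) rep_len(types, n_as) else character(0)

  n_near <- cfg$n_target_pairs + cfg$n_near_decoys
  n_far <- cfg$n_far_decoys
  if (n_near + n_far > cfg$n_lincrna_genes)
    stop("n_lincrna_genes too small for the requested target/decoy placement")
  linc_roles <- rep("generic", cfg$n_lincrna_genes)
  if (cfg$n_lincrna_genes > 0)
    linc_roles[seq_len(min(n_near + n_far, cfg$n_lincrna_genes))] <-
      c(rep("near", n_near), rep("far", n_far))

  genes <- list()
  events <- list()
  placement <- list()
  gene_i <- 0L
  linc_i <- 0L
  chrom_i <- 0L
  cursor <- 0
  chrom_lengths <- numeric(0)
  n_units <- max(cfg$n_genes, cfg$n_lincrna_genes)

  for (u in seq_len(n_units)) {
    if ((u - 1L) %% max(cfg$genes_per_chrom, 1L) == 0L) {
      chrom_i <- chrom_i + 1L
      cursor <- 150000
    }
    chrom <- sprintf("chr%d", chrom_i)
    strand <- sample(c("+", "-"), 1L)
    paired_gene <- NA_character_

    if (gene_i < cfg$n_genes) {
      gene_i <- gene_i + 1L
      gid <- sprintf("G%03d", gene_i)
      n_ex <- sample(cfg$n_exons_range[1L]:cfg$n_exons_range[2L], 1L)
      ex <- random_exons(cursor, n_ex)
      t1 <- transcript_model(paste0(gid, ".1"), gid, chrom, strand, ex)
      txs <- list(t1)
      if (gene_i <= n_as) {
        type <- as_types[gene_i]
        v <- plant_event_variant(ex, type, strand)
        txs <- c(txs, list(transcript_model(paste0(gid, ".2"), gid, chrom,
                                            strand, v)))
        events[[length(events) + 1L]] <-
          data.frame(gene_id = gid, event_type = type, stringsAsFactors = FALSE)
      }
      genes[[gid]] <- gene_model(gid, "protein_coding", txs)
      cursor <- max(ex[, 2L])
      paired_gene <- gid
    }

    if (linc_i < cfg$n_lincrna_genes) {
      linc_i <- linc_i + 1L
      lid <- sprintf("LNC%03d", linc_i)
      role <- linc_roles[linc_i]
      gap <- if (role == "near") round(stats::runif(1L, 20000, 60000))
        else round(stats::runif(1L, 120000, 180000))
      lnc_start <- cursor + gap
      lnc_ex <- random_exons(lnc_start, sample(1:2, 1L),
                             exon_range = c(300, 800))
      lt <- transcript_model(paste0(lid, ".1"), lid, chrom,
                             sample(c("+", "-"), 1L), lnc_ex)
      genes[[lid]] <- gene_model(lid, "noncoding", list(lt))
      placement[[length(placement) + 1L]] <- data.frame(
        linc_tx_id = paste0(lid, ".1"), linc_gene_id = lid,
        paired_gene_id = if (is.na(paired_gene)) NA_character_ else paired_gene,
        gap_bp = gap, role = role, stringsAsFactors = FALSE)
      cursor <- max(lnc_ex[, 2L])
    }

    cursor <- cursor + 250000
    if (cursor > cfg$chrom_length)
      stop("capacity error: chromosome length ", cfg$chrom_length,
           " too short for ", cfg$genes_per_chrom, " gene units per chromosome")
    chrom_lengths[chrom] <- cfg$chrom_length
  }

  truth <- list(
    planted_events = if (length(events)) do.call(rbind, events) else
      data.frame(gene_id = character(0), event_type = character(0),
                 stringsAsFactors = FALSE),
    linc_placement = if (length(placement)) do.call(rbind, placement) else
      data.frame(linc_tx_id = character(0), linc_gene_id = character(0),
                 paired_gene_id = character(0), gap_bp = numeric(0),
                 role = character(0), stringsAsFactors = FALSE),
    seed = cfg$seed)
  list(genes = genes, chrom_lengths = chrom_lengths, truth = truth)
}

#' Simulate chimeric long-read alignments with planted fusion classes
#'
#' Each planted read either satisfies all four fusion criteria
#' (`true_fusion`) or violates exactly one of them: `fails_coverage` (one
#' locus maps less than 10\% of the query), `fails_combined` (combined
#' query coverage below 99\%), `fails_distance` (loci less than 100 kb
#' apart), `fails_support` (fewer than 2 junction-spanning short reads).
#' Ordinary single-locus reads are labelled `non_fusion`. A junction
#' support table (query_id, s, a, b) accompanies the alignments.
#'
#' @param annotation result of [simulate_reference()] (or its `genes` list).
#' @param cfg a [sim_config()].
#' @return list with `alignments` (list of [chimeric_alignment()]),
#'   `junctions` (data.frame query_id/s/a/b) and `truth` (data.frame
#'   query_id/status plus the seed as attribute).
#' @export
simulate_fusion_alignments <- function(annotation, cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  genes <- if (is.list(annotation) && !is.null(annotation$genes))
    annotation$genes else annotation
  coding <- Filter(function(g) g$biotype == "protein_coding", genes)
  if (length(coding) < 2L)
    stop("capacity error: need at least 2 coding genes for fusion simulation")
  set.seed(cfg$seed + 1L)
  L <- cfg$read_length
  classes <- c(rep("true_fusion", cfg$n_true_fusions),
               rep("fails_coverage", cfg$n_fails_coverage),
               rep("fails_combined", cfg$n_fails_combined),
               rep("fails_distance", cfg$n_fails_distance),
               rep("fails_support", cfg$n_fails_support),
               rep("non_fusion", cfg$n_non_fusion))
  classes <- sample(classes)
  n <- length(classes)

  locus_at <- function(g, len) {
    s <- unname(g$transcripts[[1L]]$exons[1L, 1L])
    c(start = s, end = s + len)
  }
  alignments <- vector("list", n)
  junctions <- vector("list", n)
  status <- classes
  for (i in seq_len(n)) {
    qid <- sprintf("read_%04d", i)
    cls <- classes[i]
    gi <- sample(length(coding), 2L)
    gA <- coding[[gi[1L]]]; gB <- coding[[gi[2L]]]
    s_count <- round(stats::runif(1L, 5, 15))
    a_count <- round(s_count * stats::runif(1L, 0.5, 1.5))
    b_count <- round(s_count * stats::runif(1L, 0.5, 1.5))
    if (cls == "non_fusion") {
      lc <- locus_at(gA, L)
      segs <- list(aligned_segment(0, L, gA$chrom, gA$strand,
                                   lc[["start"]], lc[["end"]]))
      s_count <- 0; a_count <- 0; b_count <- 0
    } else if (cls == "fails_distance") {
      # two loci on one chromosome, 40-80 kb apart; all else passes
      lcA <- locus_at(gA, L / 2)
      gap <- round(stats::runif(1L, 40000, 80000))
      segs <- list(
        aligned_segment(0, L / 2, gA$chrom, gA$strand,
                        lcA[["start"]], lcA[["end"]]),
        aligned_segment(L / 2, L, gA$chrom, gA$strand,
                        lcA[["end"]] + gap, lcA[["end"]] + gap + L / 2))
    } else {
      lcA_len <- switch(cls,
                        fails_coverage = 0.95 * L,
                        fails_combined = 0.50 * L,
                        0.50 * L)
      lcB_q <- switch(cls,
                      fails_coverage = c(0.95 * L, 0.995 * L),
                      fails_combined = c(0.50 * L, 0.95 * L),
                      c(0.50 * L, L))
      segs <- list(
        aligned_segment(0, lcA_len, gA$chrom, gA$strand,
                        locus_at(gA, lcA_len)[["start"]],
                        locus_at(gA, lcA_len)[["end"]]),
        aligned_segment(lcB_q[1L], lcB_q[2L], gB$chrom, gB$strand,
                        locus_at(gB, diff(lcB_q))[["start"]],
                        locus_at(gB, diff(lcB_q))[["end"]]))
      if (cls == "fails_support") s_count <- sample(0:1, 1L)
    }
    alignments[[i]] <- chimeric_alignment(qid, L, segs)
    junctions[[i]] <- data.frame(query_id = qid, s = s_count, a = a_count,
                                 b = b_count, stringsAsFactors = FALSE)
  }
  truth <- data.frame(query_id = sprintf("read_%04d", seq_len(n)),
                      status = status, stringsAsFactors = FALSE)
  list(alignments = alignments,
       junctions = do.call(rbind, junctions),
       truth = truth)
}

#' Simulate an expression matrix with planted lincRNA target pairs
#'
#' Planted target pairs share a latent log-normal expression profile with
#' small multiplicative jitter, re-drawn until the realised Pearson
#' correlation and p-value satisfy the detection thresholds; they use
#' lincRNAs placed within the co-location window. Decoys violate exactly
#' one condition: "far" decoys are equally correlated but placed beyond the
#' window, "near" decoys are co-located but re-drawn until uncorrelated.
#' All other features receive independent profiles.
#'
#' @param annotation result of [simulate_reference()].
#' @param cfg a [sim_config()].
#' @param params the [target_params()] the detector will use (the generator
#'   guarantees planted truth is consistent with these thresholds).
#' @return list with `expr` (matrix features x samples), `truth` (list with
#'   `target_pairs` and `decoy_pairs` data.frames).
#' @export
simulate_expression_with_targets <- function(annotation, cfg,
                                             params = target_params()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (cfg$n_expression_samples < 3L)
    stop("correlation is degenerate with fewer than 3 samples")
  set.seed(cfg$seed + 2L)
  genes <- annotation$genes
  placement <- annotation$truth$linc_placement
  ns <- cfg$n_expression_samples
  linc_ids <- placement$linc_tx_id
  gene_ids <- vapply(Filter(function(g) g$biotype == "protein_coding", genes),
                     `[[`, "", "gene_id")
  features <- c(linc_ids, gene_ids)
  expr <- matrix(0, nrow = length(features), ncol = ns,
                 dimnames = list(features,
                                 sprintf("S%02d", seq_len(ns))))
  base_profile <- function() exp(stats::rnorm(ns, mean = log(50),
                                              sd = 1)) *
    exp(stats::rnorm(ns, sd = cfg$expression_sigma))
  for (f in features) expr[f, ] <- base_profile()

  near <- placement[placement$role == "near" & !is.na(placement$paired_gene_id), ]
  far <- placement[placement$role == "far" & !is.na(placement$paired_gene_id), ]
  if (nrow(near) < cfg$n_target_pairs + cfg$n_near_decoys ||
      nrow(far) < cfg$n_far_decoys)
    stop("annotation does not contain enough placed lincRNAs; regenerate the ",
         "reference with a larger n_lincrna_genes")
  targets <- near[seq_len(cfg$n_target_pairs), , drop = FALSE]
  near_decoys <- near[cfg$n_target_pairs + seq_len(cfg$n_near_decoys), ,
                      drop = FALSE]
  far_decoys <- far[seq_len(cfg$n_far_decoys), , drop = FALSE]

  plant_correlated <- function(linc, gene) {
    repeat {
      z <- exp(stats::rnorm(ns, mean = log(80), sd = 1.2))
      x <- z * exp(stats::rnorm(ns, sd = 0.05))
      y <- z * exp(stats::rnorm(ns, sd = 0.05))
      ct <- stats::cor.test(x, y)
      if (ct$estimate > params$r_threshold && ct$p.value < params$p_threshold) {
        expr[linc, ] <<- x
        expr[gene, ] <<- y
        break
      }
    }
  }
  plant_uncorrelated <- function(linc, gene) {
    repeat {
      x <- base_profile(); y <- base_profile()
      if (abs(stats::cor(x, y)) < 0.8) {
        expr[linc, ] <<- x
        expr[gene, ] <<- y
        break
      }
    }
  }
  for (k in seq_len(nrow(targets)))
    plant_correlated(targets$linc_tx_id[k], targets$paired_gene_id[k])
  for (k in seq_len(nrow(far_decoys)))
    plant_correlated(far_decoys$linc_tx_id[k], far_decoys$paired_gene_id[k])
  for (k in seq_len(nrow(near_decoys)))
    plant_uncorrelated(near_decoys$linc_tx_id[k], near_decoys$paired_gene_id[k])

  truth <- list(
    target_pairs = data.frame(lincRNA_id = targets$linc_tx_id,
                              gene_id = targets$paired_gene_id,
                              stringsAsFactors = FALSE),
    decoy_pairs = rbind(
      data.frame(lincRNA_id = far_decoys$linc_tx_id,
                 gene_id = far_decoys$paired_gene_id, reason = "too_far",
                 stringsAsFactors = FALSE),
      data.frame(lincRNA_id = near_decoys$linc_tx_id,
                 gene_id = near_decoys$paired_gene_id, reason = "uncorrelated",
                 stringsAsFactors = FALSE)),
    seed = cfg$seed)
  list(expr = expr, truth = truth)
}

#' Simulate per-sample lincRNA presence catalogs
#'
#' Plants four lincRNA classes: cancer-specific (present in at least one
#' cancer sample, absent from the normal sample and the reference catalog),
#' reference-listed (in cancer samples and the reference catalog), normal
#' only, and ubiquitous. The truth set of cancer-specific lincRNAs contains
#' exactly the first class.
#'
#' @param annotation result of [simulate_reference()].
#' @param cfg a [sim_config()].
#' @return list with `presence` (named list of id sets, first element the
#'   normal sample), `reference_catalog` (character vector) and `truth`
#'   (list with `specific_lincRNAs`).
#' @export
simulate_presence_catalogs <- function(annotation, cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed + 3L)
  placement <- annotation$truth$linc_placement
  ids <- placement$linc_tx_id
  need <- cfg$n_specific + cfg$n_in_reference + cfg$n_normal_only +
    cfg$n_ubiquitous
  if (length(ids) < need)
    stop("capacity error: ", need, " planted lincRNAs requested but only ",
         length(ids), " lincRNA genes in the annotation")
  ids <- sample(ids, need)
  grp <- rep(c("specific", "in_reference", "normal_only", "ubiquitous"),
             c(cfg$n_specific, cfg$n_in_reference, cfg$n_normal_only,
               cfg$n_ubiquitous))
  samples <- cfg$sample_names
  cancer <- samples[-1L]
  presence <- stats::setNames(vector("list", length(samples)), samples)
  presence[] <- list(character(0))
  reference_catalog <- character(0)
  for (k in seq_along(ids)) {
    id <- ids[k]
    in_cancers <- sample(cancer, sample(seq_along(cancer), 1L))
    if (grp[k] == "specific") {
      for (s in in_cancers) presence[[s]] <- c(presence[[s]], id)
    } else if (grp[k] == "in_reference") {
      for (s in in_cancers) presence[[s]] <- c(presence[[s]], id)
      reference_catalog <- c(reference_catalog, id)
    } else if (grp[k] == "normal_only") {
      presence[["normal"]] <- c(presence[["normal"]], id)
    } else {
      for (s in samples) presence[[s]] <- c(presence[[s]], id)
    }
  }
  presence <- lapply(presence, sort)
  list(presence = presence,
       reference_catalog = sort(reference_catalog),
       truth = list(specific_lincRNAs = sort(ids[grp == "specific"]),
                    seed = cfg$seed))
}

#' Simulate hairpin and lincRNA sequences with planted pre-miRNA hits
#'
#' Half of the hairpins are exact 70-mer substrings of a lincRNA sequence
#' (planted hits, alternating forward and reverse-complement orientation);
#' the other half are independent random sequences (planted non-hits).
#'
#' @param cfg a [sim_config()].
#' @param n_lincrnas,n_hairpins,lincrna_length,hairpin_length sizes.
#' @return list with `hairpins`, `lincrna_seqs` (named character vectors)
#'   and `truth` (data.frame hairpin_id/lincRNA_id/strand for planted hits).
#' @export
simulate_premirna_sequences <- function(cfg, n_lincrnas = 4, n_hairpins = 6,
                                        lincrna_length = 800,
                                        hairpin_length = 70) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed + 4L)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  lnc <- stats::setNames(vapply(seq_len(n_lincrnas), function(i)
    rand_seq(lincrna_length), ""), sprintf("lnc_seq_%d", seq_len(n_lincrnas)))
  n_hits <- floor(n_hairpins / 2)
  hp <- character(n_hairpins)
  truth <- list()
  for (i in seq_len(n_hairpins)) {
    if (i <= n_hits) {
      j <- ((i - 1L) %% n_lincrnas) + 1L
      at <- sample(lincrna_length - hairpin_length, 1L)
      sub <- substr(lnc[[j]], at, at + hairpin_length - 1L)
      strand <- if (i %% 2L == 0L) "-" else "+"
      if (strand == "-")
        sub <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(sub)))
      hp[i] <- sub
      truth[[length(truth) + 1L]] <- data.frame(
        hairpin_id = sprintf("hairpin_%d", i),
        lincRNA_id = names(lnc)[j], strand = strand, stringsAsFactors = FALSE)
    } else {
      hp[i] <- rand_seq(hairpin_length)
    }
  }
  names(hp) <- sprintf("hairpin_%d", seq_len(n_hairpins))
  list(hairpins = hp, lincrna_seqs = lnc,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(hairpin_id = character(0), lincRNA_id = character(0),
                    strand = character(0), stringsAsFactors = FALSE))
}

#' Simulate TSS-anchored peak sets
#'
#' Emits one peak set in which a configurable fraction of annotated
#' transcripts has a peak containing its TSS; the remaining transcripts'
#' nearest peaks are placed a known distance away.
#'
#' @param annotation result of [simulate_reference()].
#' @param cfg a [sim_config()].
#' @param in_peak_fraction fraction of transcripts whose TSS lies inside a
#'   peak.
#' @param peak_halfwidth half-width of each peak in bp.
#' @return list with `peaks` (a [peak_set()]) and `truth` (data.frame
#'   transcript_id / in_peak).
#' @export
simulate_tss_peaks <- function(annotation, cfg, in_peak_fraction = 0.7,
                               peak_halfwidth = 25) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed + 5L)
  txs <- annotation_transcripts(annotation$genes)
  n <- length(txs)
  in_peak <- stats::runif(n) < in_peak_fraction
  rows <- lapply(seq_len(n), function(i) {
    t <- txs[[i]]
    tss <- tss_of(t)
    center <- if (in_peak[i]) tss else tss + peak_halfwidth +
      round(stats::runif(1L, 50, 500))
    data.frame(chrom = t$chrom, start = center - peak_halfwidth,
               end = center + peak_halfwidth + 1, stringsAsFactors = FALSE)
  })
  list(peaks = peak_set("CAGE", do.call(rbind, rows)),
       truth = data.frame(
         transcript_id = vapply(txs, `[[`, "", "transcript_id"),
         in_peak = in_peak, stringsAsFactors = FALSE))
}

#' Simulate a per-read QC metadata table
#'
#' One row per circular-consensus read with primer/poly-A detection flags
#' and read length; a read with 5' primer, 3' primer and poly-A is
#' full-length non-chimeric (FLNC).
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns `sample`, `read_id`, `has_5p`, `has_3p`,
#'   `has_polyA`, `length`.
#' @export
simulate_qc_metadata <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed + 6L)
  do.call(rbind, lapply(cfg$sample_names, function(s) {
    n <- cfg$n_ccs
    data.frame(sample = s,
               read_id = sprintf("%s_ccs_%d", s, seq_len(n)),
               has_5p = stats::runif(n) < 0.9,
               has_3p = stats::runif(n) < 0.93,
               has_polyA = stats::runif(n) < 0.9,
               length = round(stats::rnorm(n, 2500, 500)),
               stringsAsFactors = FALSE)
  }))
}
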