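#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file containing one) with the
#' keys: `seed` (integer, mandatory), `out_dir` (output directory),
#' `synthetic` (logical; when TRUE all inputs are generated by the
#' synthetic-data module), `sim` (list of [sim_config()] overrides),
#' `fusion` (list of [fusion_params()] overrides), `targets` (list of
#' [target_params()] overrides), `inputs` (named list of input file paths
#' for non-synthetic runs) and `log_level`. Unknown keys are rejected.
#'
#' @param config named list or path to a YAML file.
#' @return the validated configuration list with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("seed", "out_dir", "synthetic", "sim", "fusion", "targets",
             "inputs", "log_level")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) stop("configuration key 'seed' is mandatory")
  if (is.null(config$out_dir)) config$out_dir <- "longtrx_out"
  if (is.null(config$synthetic)) config$synthetic <- TRUE
  if (is.null(config$sim)) config$sim <- list()
  if (is.null(config$fusion)) config$fusion <- list()
  if (is.null(config$targets)) config$targets <- list()
  if (is.null(config$inputs)) config$inputs <- list()
  if (is.null(config$log_level)) config$log_level <- "INFO"
  for (blk in c("sim", "fusion", "targets"))
    if (!is.list(config[[blk]]))
      stop("configuration key '", blk, "' must be a list")
  bad <- setdiff(names(config$sim),
                 setdiff(names(formals(sim_config)), "seed"))
  if (length(bad))
    stop("unknown key(s) in 'sim' block: ", paste(bad, collapse = ", "))
  bad <- setdiff(names(config$fusion), names(formals(fusion_params)))
  if (length(bad))
    stop("unknown key(s) in 'fusion' block: ", paste(bad, collapse = ", "))
  bad <- setdiff(names(config$targets), names(formals(target_params)))
  if (length(bad))
    stop("unknown key(s) in 'targets' block: ", paste(bad, collapse = ", "))
  config
}

log_msg <- function(level, ..., config) {
  levels <- c(DEBUG = 1, INFO = 2, WARN = 3, ERROR = 4)
  if (levels[[level]] >= levels[[config$log_level]])
    message(sprintf("[%s] %s", level, paste0(...)))
}

# Generate the full synthetic input bundle in memory.
synthetic_bundle <- function(cfg, tparams) {
  ref <- simulate_reference(cfg)
  fus <- simulate_fusion_alignments(ref, cfg)
  expr <- simulate_expression_with_targets(ref, cfg, tparams)
  pres <- simulate_presence_catalogs(ref, cfg)
  mirna <- simulate_premirna_sequences(cfg)
  peaks <- simulate_tss_peaks(ref, cfg)
  qc <- simulate_qc_metadata(cfg)
  list(ref = ref, fus = fus, expr = expr, pres = pres, mirna = mirna,
       peaks = peaks, qc = qc)
}

write_synthetic_inputs <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gtf(bundle$ref$genes, file.path(dir, "annotation.gtf"))
  write_paf(bundle$fus$alignments, file.path(dir, "alignments.paf"))
  write_tsv(bundle$fus$junctions, file.path(dir, "junctions.tsv"))
  write_expression_tsv(bundle$expr$expr, file.path(dir, "expression.tsv"))
  write_bed(bundle$peaks$peaks, file.path(dir, "peaks.bed"))
  write_tsv(bundle$qc, file.path(dir, "qc_metadata.tsv"))
  for (s in names(bundle$pres$presence))
    writeLines(bundle$pres$presence[[s]],
               file.path(dir, paste0("presence_", s, ".txt")))
  writeLines(bundle$pres$reference_catalog,
             file.path(dir, "reference_catalog.txt"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(bundle$mirna$hairpins),
    file.path(dir, "hairpins.fa"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(bundle$mirna$lincrna_seqs),
    file.path(dir, "lincrna_seqs.fa"))
  truth <- list(
    planted_events = bundle$ref$truth$planted_events,
    linc_placement = bundle$ref$truth$linc_placement,
    fusion_status = bundle$fus$truth,
    target_pairs = bundle$expr$truth$target_pairs,
    specific_lincRNAs = bundle$pres$truth$specific_lincRNAs,
    tss_in_peak = bundle$peaks$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

# Per-sample isoform catalogs derived from the synthetic annotation: the
# normal sample carries every isoform; each cancer sample loses the variant
# isoform of a seeded subset of the multi-isoform genes.
synthetic_catalogs <- function(ref, cfg) {
  set.seed(cfg$seed + 7L)
  genes <- ref$genes
  full <- isoform_catalog(annotation_transcripts(genes))
  catalogs <- stats::setNames(vector("list", cfg$n_samples), cfg$sample_names)
  catalogs[["normal"]] <- full
  multi <- names(Filter(function(g) length(g$transcripts) > 1L, genes))
  for (s in cfg$sample_names[-1L]) {
    cat_s <- full
    drop <- multi[stats::runif(length(multi)) < 0.4]
    for (g in drop) cat_s[[g]] <- cat_s[[g]][1L]
    catalogs[[s]] <- cat_s
  }
  catalogs
}

#' Run a pipeline stage (or the whole pipeline) from a configuration
#'
#' Subcommands: `"simulate"` writes the full synthetic input bundle plus
#' truth tables; `"classify"`, `"lncrna"`, `"splicing"`, `"fusion"` and
#' `"qc"` run one analysis stage; `"all"` runs
#' simulate, classify, lncrna, splicing, fusion and qc in order and
#' assembles a report. With `synthetic: true` (the default) all stage
#' inputs are generated from the configured seed; every run writes a
#' manifest sufficient to reproduce it.
#'
#' @param subcommand one of simulate, classify, lncrna, splicing, fusion,
#'   qc, all.
#' @param config configuration list or YAML path; see [validate_config()].
#' @return invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "classify",
                                        "lncrna", "splicing", "fusion", "qc"),
                         config) {
  subcommand <- match.arg(subcommand)
  config <- validate_config(config)
  if (!config$synthetic) {
    required <- switch(subcommand,
      classify = c("annotation_gtf", "query_gtf", "peaks_bed"),
      fusion = c("annotation_gtf", "alignments_paf", "junctions_tsv"),
      lncrna = c("annotation_gtf", "expression_tsv"),
      splicing = "annotation_gtf",
      qc = "qc_metadata_tsv",
      character(0))
    for (key in required) {
      p <- config$inputs[[key]]
      if (is.null(p)) stop("missing input path: inputs$", key)
      if (!file.exists(p)) stop("input file not found: ", p, " (inputs$",
                                key, ")")
    }
  }
  cfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  fparams <- do.call(fusion_params, config$fusion)
  tparams <- do.call(target_params, config$targets)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  stages <- list()

  bundle <- NULL
  need_bundle <- config$synthetic
  if (need_bundle) {
    log_msg("INFO", "generating synthetic inputs (seed ", config$seed, ")",
            config = config)
    bundle <- synthetic_bundle(cfg, tparams)
  }

  if (subcommand %in% c("simulate", "all")) {
    in_dir <- file.path(config$out_dir, "inputs")
    write_synthetic_inputs(bundle, in_dir)
    outputs$inputs <- in_dir
    if (subcommand == "simulate") {
      manifest <- list(package = "longtrx",
                       version = as.character(utils::packageVersion("longtrx")),
                       seed = config$seed, subcommand = subcommand,
                       config = config[c("seed", "synthetic", "sim", "fusion",
                                         "targets")])
      jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      return(invisible(outputs))
    }
  }

  load_annotation <- function() {
    if (config$synthetic) bundle$ref$genes
    else parse_gtf(config$inputs$annotation_gtf)
  }

  if (subcommand %in% c("classify", "all")) {
    ann <- load_annotation()
    if (config$synthetic) {
      queries <- annotation_transcripts(ann)
      peaks <- bundle$peaks$peaks
    } else {
      queries <- annotation_transcripts(parse_gtf(config$inputs$query_gtf))
      peaks <- read_peaks_bed(config$inputs$peaks_bed)
    }
    novelty <- classify_transcripts(queries, ann)
    tssd <- tss_peak_distances(queries, peaks)
    stages$novelty <- novelty
    stages$tss_distances <- tssd$records
    stages$tss_distance_summary <- tssd$summary
    log_msg("INFO", "classified ", nrow(novelty), " transcripts",
            config = config)
  }

  if (subcommand %in% c("lncrna", "all")) {
    if (config$synthetic) {
      pres <- bundle$pres
      specific <- cancer_specific_lincRNAs(pres$presence[-1L],
                                           pres$presence[[1L]],
                                           pres$reference_catalog)
      placement <- bundle$ref$truth$linc_placement
      lincs <- lapply(placement$linc_gene_id, function(g)
        bundle$ref$genes[[g]]$transcripts[[1L]])
      coding <- Filter(function(g) g$biotype == "protein_coding",
                       bundle$ref$genes)
      targets <- predict_targets(lincs, coding, bundle$expr$expr, tparams)
      hits <- find_premirna(bundle$mirna$hairpins, bundle$mirna$lincrna_seqs)
      stages$specific_lincRNAs <- data.frame(lincRNA_id = specific,
                                             stringsAsFactors = FALSE)
      stages$lncrna_targets <- targets
      stages$premirna_hits <- hits
    } else {
      ann <- load_annotation()
      expr <- read_expression_tsv(config$inputs$expression_tsv)
      noncoding <- Filter(function(g) g$biotype == "noncoding", ann)
      lincs <- unlist(lapply(noncoding, `[[`, "transcripts"),
                      recursive = FALSE, use.names = FALSE)
      lincs <- Filter(function(t) classify_lincRNA(t, ann), lincs)
      coding <- Filter(function(g) g$biotype == "protein_coding", ann)
      stages$lncrna_targets <- predict_targets(lincs, coding, expr, tparams)
    }
  }

  if (subcommand %in% c("splicing", "all")) {
    ann <- load_annotation()
    events <- enumerate_as_events_all(ann)
    stages$as_events <- events
    if (config$synthetic) {
      catalogs <- synthetic_catalogs(bundle$ref, cfg)
      scores <- divergence_score(catalogs[[1L]], catalogs[-1L])
      stages$divergence <- scores
    }
  }

  if (subcommand %in% c("fusion", "all")) {
    if (config$synthetic) {
      alignments <- bundle$fus$alignments
      junctions <- bundle$fus$junctions
      ann <- bundle$ref$genes
    } else {
      alignments <- parse_alignments(config$inputs$alignments_paf, "paf")
      junctions <- utils::read.delim(config$inputs$junctions_tsv,
                                     stringsAsFactors = FALSE)
      ann <- load_annotation()
    }
    det <- detect_candidates(alignments, fparams)
    support <- count_junction_support(det$candidates, junctions)
    tiers <- apply_support_filters(support, fparams)
    genes_per_cand <- vapply(det$candidates, function(cand) {
      labs <- assign_parental_genes(cand, ann)
      paste(labs, collapse = "|")
    }, "")
    tiers$parental_genes <- genes_per_cand
    stages$fusion_audit <- det$audit
    stages$fusions <- tiers
    log_msg("INFO", sum(tiers$tier1), " tier-1 fusion(s) detected",
            config = config)
  }

  if (subcommand %in% c("qc", "all")) {
    meta <- if (config$synthetic) bundle$qc
      else utils::read.delim(config$inputs$qc_metadata_tsv,
                             stringsAsFactors = FALSE)
    stages$qc <- qc_summary(meta)
  }

  report_dir <- file.path(config$out_dir, "report")
  assemble_report(stages, report_dir,
                  config = config[c("seed", "synthetic", "sim", "fusion",
                                    "targets")],
                  seed = config$seed)
  outputs$report <- report_dir
  outputs$stages <- names(stages)
  invisible(outputs)
}
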