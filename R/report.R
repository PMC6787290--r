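#' Quality-control summary of long-read metadata
#'
#' Accepts either a per-read metadata table (columns `sample`, `has_5p`,
#' `has_3p`, `has_polyA`, `length`; a read with all three features is a
#' full-length non-chimeric read, FLNC) or a per-sample counts table
#' (columns `sample`, `ccs`, `flnc`, optionally `reads_5p`, `reads_3p`,
#' `reads_polyA`, `mean_flnc_length`). The FLNC/CCS ratio is rounded
#' half-even to 2 decimals.
#'
#' @param x data.frame in one of the two forms above.
#' @return data.frame with one row per sample: `sample`, `ccs`, `reads_5p`,
#'   `reads_3p`, `reads_polyA`, `flnc`, `mean_flnc_length`,
#'   `flnc_ccs_ratio` and `flnc_ccs_display` (ratio with trailing zeros
#'   trimmed, as conventionally printed).
#' @export
qc_summary <- function(x) {
  if (all(c("ccs", "flnc") %in% names(x))) {
    out <- data.frame(
      sample = x$sample,
      ccs = x$ccs,
      reads_5p = if ("reads_5p" %in% names(x)) x$reads_5p else NA_real_,
      reads_3p = if ("reads_3p" %in% names(x)) x$reads_3p else NA_real_,
      reads_polyA = if ("reads_polyA" %in% names(x)) x$reads_polyA else NA_real_,
      flnc = x$flnc,
      mean_flnc_length = if ("mean_flnc_length" %in% names(x))
        x$mean_flnc_length else NA_real_,
      stringsAsFactors = FALSE)
  } else if (all(c("sample", "has_5p", "has_3p", "has_polyA") %in% names(x))) {
    out <- do.call(rbind, lapply(split(x, x$sample), function(s) {
      flnc <- s$has_5p & s$has_3p & s$has_polyA
      data.frame(sample = s$sample[1L], ccs = nrow(s),
                 reads_5p = sum(s$has_5p), reads_3p = sum(s$has_3p),
                 reads_polyA = sum(s$has_polyA), flnc = sum(flnc),
                 mean_flnc_length = if (any(flnc)) mean(s$length[flnc])
                   else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  } else {
    stop("'x' must be a per-read metadata table or a per-sample counts table")
  }
  if (any(out$ccs <= 0))
    stop("undefined FLNC/CCS ratio: sample with ccs = 0")
  if (any(out$flnc > out$ccs))
    stop("flnc count exceeds ccs count")
  out$flnc_ccs_ratio <- round(out$flnc / out$ccs, 2)
  out$flnc_ccs_display <- sub("0+$", "", sprintf("%.2f", out$flnc_ccs_ratio))
  out$flnc_ccs_display <- sub("\\.$", "", out$flnc_ccs_display)
  rownames(out) <- NULL
  out
}

#' Assemble a pipeline report directory
#'
#' Writes one TSV per stage output, a human-readable `summary.txt` with a
#' section per executed stage, and a `manifest.json` echoing the
#' configuration, seed and package version. Output is deterministic: stages
#' are written in sorted name order and the timestamp is suppressed by
#' default.
#'
#' @param stages named list of data.frames (one per executed stage).
#' @param dir output directory (created if needed).
#' @param config configuration list echoed into the manifest.
#' @param seed seed echoed into the manifest.
#' @param timestamp include a timestamp in the manifest (default FALSE so
#'   reruns are byte-identical).
#' @return invisibly, the manifest list.
#' @export
assemble_report <- function(stages, dir, config = list(), seed = NA,
                            timestamp = FALSE) {
  stopifnot(length(stages) >= 1L, !is.null(names(stages)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stage_names <- sort(names(stages))
  lines <- c("longtrx pipeline report", strrep("=", 23), "")
  for (s in stage_names) {
    df <- stages[[s]]
    write_tsv(df, file.path(dir, paste0(s, ".tsv")))
    lines <- c(lines, paste0("## ", s),
               sprintf("rows: %d, columns: %s", nrow(df),
                       paste(names(df), collapse = ", ")), "")
  }
  manifest <- list(
    package = "longtrx",
    version = as.character(utils::packageVersion("longtrx")),
    seed = seed,
    stages = stage_names,
    config = config)
  if (timestamp) manifest$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(manifest)
}
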