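#' Parameters for lncRNA target-gene prediction
#'
#' A coding gene is called a target of a lincRNA when the two are strongly
#' co-expressed (Pearson r above `r_threshold` with two-sided p below
#' `p_threshold`) and co-located (gap between the feature spans below
#' `window`). Note that with very few samples the two expression thresholds
#' can be jointly unsatisfiable (e.g. at n = 5, r > 0.95 gives p about
#' 0.013); they are applied as configured and independently adjustable.
#'
#' @param r_threshold minimum Pearson correlation (exclusive), default 0.95.
#' @param p_threshold maximum two-sided p-value (exclusive), default 0.001.
#' @param window maximum genomic gap in bp (exclusive), default 100000
#'   (100 kb upstream or downstream).
#' @return object of class `TargetParams`.
#' @export
target_params <- function(r_threshold = 0.95, p_threshold = 0.001,
                          window = 1e5) {
  stopifnot(r_threshold > 0, r_threshold <= 1, window > 0, p_threshold > 0)
  structure(list(r_threshold = r_threshold, p_threshold = p_threshold,
                 window = window), class = "TargetParams")
}

#' Consensus non-coding filter
#'
#' Keeps only candidates called non-coding by all four coding-potential
#' predictors (CNCI, PLEK, CPC, PfamScan); a transcript predicted to have
#' coding potential by any single tool is filtered out.
#'
#' @param candidates character vector of transcript ids.
#' @param calls data.frame as returned by [read_coding_calls()]: rownames =
#'   transcript ids, columns CNCI/PLEK/CPC/PfamScan with values `"coding"`
#'   or `"noncoding"`.
#' @return character vector of kept transcript ids (order preserved).
#' @export
consensus_noncoding_filter <- function(candidates, calls) {
  predictors <- c("CNCI", "PLEK", "CPC", "PfamScan")
  missing_cols <- setdiff(predictors, colnames(calls))
  if (length(missing_cols))
    stop("call table lacks predictor(s): ", paste(missing_cols, collapse = ", "))
  absent <- setdiff(candidates, rownames(calls))
  if (length(absent))
    stop("no coding-potential calls for candidate(s): ",
         paste(absent, collapse = ", "))
  bad <- !as.matrix(calls[candidates, predictors, drop = FALSE]) %in%
    c("coding", "noncoding")
  if (any(bad)) stop("call table contains values other than coding/noncoding")
  keep <- apply(calls[candidates, predictors, drop = FALSE] == "noncoding",
                1L, all)
  candidates[keep]
}

#' Is a lncRNA intergenic (a lincRNA)?
#'
#' A long non-coding transcript is classified as intergenic when its genomic
#' span overlaps no protein-coding gene span on either strand (so a lncRNA
#' inside a coding gene's intron, or antisense to one, is not a lincRNA).
#' Overlap with non-coding genes is ignored.
#'
#' @param lnc a [transcript_model()].
#' @param annotation list of [gene_model()] objects.
#' @return logical scalar.
#' @export
classify_lincRNA <- function(lnc, annotation) {
  s <- min(lnc$exons[, 1L]); e <- max(lnc$exons[, 2L])
  for (g in annotation) {
    if (g$biotype != "protein_coding") next
    if (g$chrom != lnc$chrom) next
    if (s < g$span[["end"]] && g$span[["start"]] < e) return(FALSE)
  }
  TRUE
}

#' Cancer-cell-specific lincRNAs by set logic
#'
#' A lincRNA is specific to the cancer cells when it is detected in the
#' cancer samples but absent from the normal-like sample and from the
#' reference lincRNA catalog. By default "detected in the cancer samples"
#' is read permissively (present in at least one cancer sample, the union);
#' `mode = "intersection"` instead requires presence in every cancer sample.
#'
#' @param cancer_sets list of character vectors of lincRNA ids, one per
#'   cancer sample.
#' @param normal_set character vector of ids detected in the normal sample.
#' @param reference_catalog character vector of ids in the reference
#'   lincRNA catalog.
#' @param mode `"union"` (default) or `"intersection"`.
#' @return sorted character vector of specific lincRNA ids.
#' @export
cancer_specific_lincRNAs <- function(cancer_sets, normal_set = character(0),
                                     reference_catalog = character(0),
                                     mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(length(cancer_sets) >= 1L)
  pool <- if (mode == "union") unique(unlist(cancer_sets, use.names = FALSE))
    else Reduce(intersect, cancer_sets)
  if (is.null(pool)) pool <- character(0)
  sort(setdiff(pool, union(normal_set, reference_catalog)))
}

#' Predict target genes of lincRNAs by co-expression and co-location
#'
#' Tests every lincRNA x coding-gene pair on the same chromosome. A pair is
#' reported when the Pearson correlation of expression across samples
#' exceeds `params$r_threshold` with a two-sided p-value (t transform of r
#' with n - 2 degrees of freedom) below `params$p_threshold`, and the gap
#' between the two feature spans (closest edges; 0 when the spans overlap)
#' is below `params$window`. Pairs involving a zero-variance expression
#' vector are skipped with a warning.
#'
#' @param lincRNAs list of [transcript_model()] objects (the lincRNAs).
#' @param genes list of [gene_model()] objects (the coding genes).
#' @param expr expression matrix with features in rows (must contain all
#'   lincRNA and gene ids) and at least 3 sample columns.
#' @param params a [target_params()].
#' @return data.frame with columns `lincRNA_id`, `gene_id`, `r`, `p`,
#'   `distance`.
#' @export
predict_targets <- function(lincRNAs, genes, expr, params = target_params()) {
  stopifnot(inherits(params, "TargetParams"))
  if (ncol(expr) < 3L)
    stop("target prediction requires at least 3 samples")
  lid <- vapply(lincRNAs, `[[`, "", "transcript_id")
  gid <- vapply(genes, `[[`, "", "gene_id")
  need <- setdiff(c(lid, gid), rownames(expr))
  if (length(need))
    stop("features missing from expression matrix: ",
         paste(need, collapse = ", "))
  out <- list()
  for (i in seq_along(lincRNAs)) {
    l <- lincRNAs[[i]]
    ls <- min(l$exons[, 1L]); le <- max(l$exons[, 2L])
    for (j in seq_along(genes)) {
      g <- genes[[j]]
      if (g$chrom != l$chrom) next
      gap <- max(g$span[["start"]] - le, ls - g$span[["end"]], 0)
      if (gap >= params$window) next
      x <- expr[lid[i], ]; y <- expr[gid[j], ]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("zero-variance expression for pair (", lid[i], ", ", gid[j],
                "); skipped")
        next
      }
      ct <- stats::cor.test(x, y, method = "pearson")
      if (ct$estimate > params$r_threshold && ct$p.value < params$p_threshold)
        out[[length(out) + 1L]] <- data.frame(
          lincRNA_id = lid[i], gene_id = gid[j],
          r = unname(ct$estimate), p = ct$p.value, distance = gap,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(lincRNA_id = character(0), gene_id = character(0),
                      r = numeric(0), p = numeric(0), distance = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$lincRNA_id, res$gene_id), ]
  rownames(res) <- NULL
  res
}

#' Search lincRNA sequences for miRNA hairpins (pre-miRNA candidates)
#'
#' Local alignment (match +1, mismatch -2, affine gaps with open and extend
#' penalties of 2.5) of every hairpin against every lincRNA sequence and its
#' reverse complement. A hit requires identity of at least `min_identity`
#' over an aligned region covering at least `min_hairpin_coverage` of the
#' hairpin length. U residues are treated as T.
#'
#' @param hairpins named character vector or `Biostrings::DNAStringSet`/
#'   `RNAStringSet` of hairpin sequences.
#' @param lincrna_seqs named character vector or `DNAStringSet` of lincRNA
#'   sequences.
#' @param min_identity default 0.90.
#' @param min_hairpin_coverage default 0.90.
#' @return data.frame with columns `hairpin_id`, `lincRNA_id`, `strand`,
#'   `identity`, `hairpin_coverage`, `score`.
#' @export
find_premirna <- function(hairpins, lincrna_seqs, min_identity = 0.90,
                          min_hairpin_coverage = 0.90) {
  as_dna <- function(x, what) {
    if (is.character(x)) {
      empty <- !nzchar(x)
      if (any(empty)) {
        warning("skipping empty ", what, " sequence(s): ",
                paste(names(x)[empty], collapse = ", "))
        x <- x[!empty]
      }
      x <- toupper(gsub("U", "T", x, ignore.case = TRUE))
      Biostrings::DNAStringSet(x)
    } else {
      Biostrings::DNAStringSet(gsub("U", "T", as.character(x)))
    }
  }
  hp <- as_dna(hairpins, "hairpin")
  lnc <- as_dna(lincrna_seqs, "lincRNA")
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  out <- list()
  for (i in seq_along(hp)) {
    for (j in seq_along(lnc)) {
      for (strand in c("+", "-")) {
        subj <- if (strand == "+") lnc[[j]] else
          Biostrings::reverseComplement(lnc[[j]])
        aln <- Biostrings::pairwiseAlignment(
          hp[[i]], subj, type = "local", substitutionMatrix = submat,
          gapOpening = 2.5, gapExtension = 2.5)
        aligned_hp <- Biostrings::width(Biostrings::pattern(aln))
        cov <- aligned_hp / length(hp[[i]])
        ident <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
        if (cov >= min_hairpin_coverage && ident >= min_identity)
          out[[length(out) + 1L]] <- data.frame(
            hairpin_id = names(hp)[i], lincRNA_id = names(lnc)[j],
            strand = strand, identity = ident, hairpin_coverage = cov,
            score = Biostrings::score(aln), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(hairpin_id = character(0), lincRNA_id = character(0),
                      strand = character(0), identity = numeric(0),
                      hairpin_coverage = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
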