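small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_genes = 20, n_lincrna_genes = 10,
             n_true_fusions = 5, n_fails_coverage = 3, n_fails_combined = 3,
             n_fails_distance = 3, n_fails_support = 3, n_non_fusion = 10,
             n_target_pairs = 2, n_near_decoys = 2, n_far_decoys = 2,
             n_specific = 3, n_in_reference = 2, n_normal_only = 2,
             n_ubiquitous = 2, n_ccs = 50, ...)
}

test_that("sim_config validates its inputs", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, n_genes = -5), ">= 0")
  expect_error(sim_config(seed = 1, n_samples = 1), "normal")
  cfg <- sim_config(seed = 1)
  expect_equal(cfg$sample_names[1], "normal")
  expect_length(cfg$sample_names, cfg$n_samples)
})

test_that("all generators are deterministic in (cfg, seed)", {
  cfg <- small_cfg(seed = 9)
  r1 <- simulate_reference(cfg); r2 <- simulate_reference(cfg)
  expect_identical(write_gtf(r1$genes), write_gtf(r2$genes))
  expect_identical(r1$truth, r2$truth)
  f1 <- simulate_fusion_alignments(r1, cfg)
  f2 <- simulate_fusion_alignments(r2, cfg)
  expect_identical(write_paf(f1$alignments), write_paf(f2$alignments))
  expect_identical(f1$junctions, f2$junctions)
  e1 <- simulate_expression_with_targets(r1, cfg)
  e2 <- simulate_expression_with_targets(r2, cfg)
  expect_identical(e1$expr, e2$expr)
  p1 <- simulate_presence_catalogs(r1, cfg)
  p2 <- simulate_presence_catalogs(r2, cfg)
  expect_identical(p1, p2)
  # a different seed changes the output
  r3 <- simulate_reference(small_cfg(seed = 10))
  expect_false(identical(write_gtf(r1$genes), write_gtf(r3$genes)))
})

test_that("simulate_reference plants the requested events and placements", {
  cfg <- small_cfg(seed = 2)
  ref <- simulate_reference(cfg)
  pe <- ref$truth$planted_events
  expect_equal(nrow(pe), round(cfg$as_event_fraction * cfg$n_genes))
  expect_true(all(pe$event_type %in% c("SE", "MXE", "A5", "A3", "AF",
                                       "AL", "RI")))
  # genes never overlap
  coding <- Filter(function(g) g$biotype == "protein_coding", ref$genes)
  spans <- do.call(rbind, lapply(ref$genes, function(g)
    data.frame(chrom = g$chrom, s = g$span[["start"]], e = g$span[["end"]])))
  for (ch in unique(spans$chrom)) {
    sp <- spans[spans$chrom == ch, ]
    sp <- sp[order(sp$s), ]
    if (nrow(sp) > 1) expect_true(all(sp$s[-1] >= sp$e[-nrow(sp)]))
  }
  # near placements are within the 100 kb window, far ones beyond it
  lp <- ref$truth$linc_placement
  expect_true(all(lp$gap_bp[lp$role == "near"] < 1e5))
  expect_true(all(lp$gap_bp[lp$role == "far"] > 1e5))
  # capacity error when the chromosome cannot hold the gene units
  expect_error(simulate_reference(small_cfg(seed = 1, chrom_length = 1e5)),
               "capacity")
  # empty annotation
  cfg0 <- sim_config(seed = 1, n_genes = 0, n_lincrna_genes = 0,
                     n_target_pairs = 0, n_near_decoys = 0, n_far_decoys = 0)
  expect_length(simulate_reference(cfg0)$genes, 0L)
})

test_that("planted fusion classes violate exactly their named criterion", {
  cfg <- small_cfg(seed = 4)
  ref <- simulate_reference(cfg)
  fus <- simulate_fusion_alignments(ref, cfg)
  expect_equal(nrow(fus$truth), length(fus$alignments))
  expect_equal(sum(fus$truth$status == "true_fusion"), cfg$n_true_fusions)
  byid <- setNames(fus$alignments,
                   vapply(fus$alignments, `[[`, "", "query_id"))
  L <- cfg$read_length
  for (i in seq_len(nrow(fus$truth))) {
    a <- byid[[fus$truth$query_id[i]]]
    status <- fus$truth$status[i]
    if (status == "non_fusion") {
      expect_length(a$segments, 1L)
      next
    }
    fracs <- vapply(a$segments, function(s)
      (s$query_end - s$query_start) / L, 0)
    qiv <- vapply(a$segments, function(s) s$query_end - s$query_start, 0)
    combined <- sum(qiv) / L   # planted segments never overlap on the query
    same_chrom <- length(unique(vapply(a$segments, `[[`, "", "chrom"))) == 1L
    if (status == "fails_coverage") expect_true(min(fracs) < 0.10)
    else expect_true(min(fracs) >= 0.10)
    if (status == "fails_combined") expect_true(combined < 0.99)
    else expect_true(combined >= 0.99)
    if (status == "fails_distance") {
      expect_true(same_chrom)
      gap <- a$segments[[2]]$target_start - a$segments[[1]]$target_end
      expect_true(abs(gap) <= 1e5)
    }
    s <- fus$junctions$s[fus$junctions$query_id == a$query_id]
    if (status == "fails_support") expect_true(s < 2)
    else if (status != "non_fusion") expect_true(s >= 2)
  }
})

test_that("planted expression pairs meet the detector thresholds", {
  cfg <- small_cfg(seed = 5)
  ref <- simulate_reference(cfg)
  params <- target_params()
  ex <- simulate_expression_with_targets(ref, cfg, params)
  expect_equal(ncol(ex$expr), cfg$n_expression_samples)
  expect_true(all(ex$expr >= 0))
  tp <- ex$truth$target_pairs
  expect_equal(nrow(tp), cfg$n_target_pairs)
  for (k in seq_len(nrow(tp))) {
    ct <- cor.test(ex$expr[tp$lincRNA_id[k], ], ex$expr[tp$gene_id[k], ])
    expect_gt(ct$estimate, params$r_threshold)
    expect_lt(ct$p.value, params$p_threshold)
  }
  dec <- ex$truth$decoy_pairs
  for (k in which(dec$reason == "uncorrelated"))
    expect_lt(abs(cor(ex$expr[dec$lincRNA_id[k], ], ex$expr[dec$gene_id[k], ])),
              0.8)
  expect_error(
    simulate_expression_with_targets(ref, small_cfg(seed = 1,
                                                    n_expression_samples = 2)),
    "degenerate")
})

test_that("presence catalogs partition planted lincRNA classes correctly", {
  cfg <- small_cfg(seed = 6)
  ref <- simulate_reference(cfg)
  pr <- simulate_presence_catalogs(ref, cfg)
  truth <- pr$truth$specific_lincRNAs
  expect_length(truth, cfg$n_specific)
  normal <- pr$presence[["normal"]]
  cancers <- pr$presence[-1]
  for (id in truth) {
    expect_true(any(vapply(cancers, function(s) id %in% s, TRUE)))
    expect_false(id %in% normal)
    expect_false(id %in% pr$reference_catalog)
  }
  # reference-listed ids are present in cancers but excluded from truth
  expect_false(any(pr$reference_catalog %in% truth))
})

test_that("planted hairpins are exact substrings with the planted strand", {
  cfg <- small_cfg(seed = 7)
  mi <- simulate_premirna_sequences(cfg)
  for (k in seq_len(nrow(mi$truth))) {
    hp <- mi$hairpins[[mi$truth$hairpin_id[k]]]
    lnc <- mi$lincrna_seqs[[mi$truth$lincRNA_id[k]]]
    if (mi$truth$strand[k] == "-")
      hp <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(hp)))
    expect_true(grepl(hp, lnc, fixed = TRUE))
  }
})
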