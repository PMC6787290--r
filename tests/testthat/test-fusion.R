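two_seg_read <- function(id = "r", qlen = 3000,
                         q1 = c(0, 1500), q2 = c(1500, 2990),
                         chrom2 = "chr1", t1 = c(1000000, 1001500),
                         t2 = c(1200000, 1201490)) {
  chimeric_alignment(id, qlen, list(
    aligned_segment(q1[1], q1[2], "chr1", "+", t1[1], t1[2]),
    aligned_segment(q2[1], q2[2], chrom2, "+", t2[1], t2[2])))
}

test_that("the three mapping criteria admit and reject as specified", {
  # fractions 0.50/0.497, combined 0.997, gap ~198.5 kb: a candidate
  res <- detect_candidates(list(two_seg_read()))
  expect_true(res$audit$candidate)
  expect_equal(length(res$candidates), 1L)
  # same geometry but loci 50 kb apart fails only the distance criterion
  near <- two_seg_read(t2 = c(1051500, 1052990))
  res <- detect_candidates(list(near))
  expect_false(res$audit$candidate)
  expect_false(res$audit$pass_distance)
  expect_true(res$audit$pass_locus_coverage)
  expect_true(res$audit$pass_combined_coverage)
  # a segment covering 5% of the query fails locus coverage
  tiny <- two_seg_read(q1 = c(0, 2840), q2 = c(2840, 2990))
  res <- detect_candidates(list(tiny))
  expect_false(res$audit$pass_locus_coverage)
  # different chromosomes always pass the distance criterion
  diff_chrom <- two_seg_read(chrom2 = "chr2", t2 = c(1000, 2490))
  expect_true(detect_candidates(list(diff_chrom))$audit$pass_distance)
  # single-segment reads are never candidates
  single <- chimeric_alignment("s", 1000, list(
    aligned_segment(0, 1000, "chr1", "+", 0, 1000)))
  expect_false(detect_candidates(list(single))$audit$multi_locus)
})

test_that("combined coverage uses the union of query intervals", {
  # heavily overlapping segments must not double-count
  overlapping <- chimeric_alignment("r", 1000, list(
    aligned_segment(0, 600, "chr1", "+", 0, 600),
    aligned_segment(100, 700, "chr2", "+", 0, 600)))
  res <- detect_candidates(list(overlapping))
  expect_false(res$audit$pass_combined_coverage)   # union is 700/1000
})

test_that("detector equals the independent brute-force evaluator", {
  cfg <- sim_config(seed = 41, n_genes = 25, n_lincrna_genes = 6,
                    n_true_fusions = 8, n_fails_coverage = 4,
                    n_fails_combined = 4, n_fails_distance = 4,
                    n_fails_support = 4, n_non_fusion = 20,
                    n_target_pairs = 2, n_near_decoys = 1, n_far_decoys = 1)
  ref <- simulate_reference(cfg)
  fus <- simulate_fusion_alignments(ref, cfg)
  res <- detect_candidates(fus$alignments)
  for (i in seq_along(fus$alignments))
    expect_equal(res$audit$candidate[i],
                 oracle_fusion_candidate(fus$alignments[[i]]),
                 info = res$audit$query_id[i])
})

test_that("raising any threshold never increases the candidate count", {
  cfg <- sim_config(seed = 42, n_genes = 25, n_lincrna_genes = 6,
                    n_target_pairs = 2, n_near_decoys = 1, n_far_decoys = 1)
  ref <- simulate_reference(cfg)
  fus <- simulate_fusion_alignments(ref, cfg)
  grid <- expand.grid(frac = c(0.05, 0.10, 0.20),
                      comb = c(0.90, 0.99, 0.999),
                      dist = c(5e4, 1e5, 2e5))
  counts <- apply(grid, 1L, function(g)
    sum(detect_candidates(fus$alignments,
                          fusion_params(min_locus_query_fraction = g["frac"],
                                        min_combined_coverage = g["comb"],
                                        min_locus_distance = g["dist"])
        )$audit$candidate))
  for (par in names(grid)) {
    for (fixed in split(seq_len(nrow(grid)), grid[setdiff(names(grid), par)])) {
      ord <- fixed[order(grid[fixed, par])]
      expect_true(all(diff(counts[ord]) <= 0))
    }
  }
})

test_that("junction support counts spanning and flanking reads", {
  cand <- detect_candidates(list(two_seg_read()))$candidates
  # pass-through of a precomputed support table
  tab <- data.frame(query_id = "r", s = 10, a = 15, b = 12)
  expect_equal(count_junction_support(cand, tab),
               data.frame(query_id = "r", s = 10, a = 15, b = 12))
  # read-level counting: junction at read position 1500
  reads <- data.frame(
    query_id = "r",
    start = c(1480, 1485, 1490, 1492, 1300, 1501),
    end = c(1520, 1512, 1508, 1500, 1499, 1700))
  sup <- count_junction_support(cand, reads, overhang = 8, flank_window = 100)
  # spanning: needs start <= 1492 and end >= 1508 -> reads 1-3
  expect_equal(sup$s, 3)
  # the read ending exactly at the junction does not span it
  expect_equal(sup$a, 5)  # all reads overlapping (1400, 1500)
  expect_equal(sup$b, 4)  # reads overlapping (1500, 1600)
})

test_that("support filters define the two tiers with safe ratio handling", {
  params <- fusion_params()
  sup <- data.frame(query_id = c("ok", "weak", "skewed", "zero"),
                    s = c(10, 1, 5, 0), a = c(15, 0, 20, 9),
                    b = c(12, 0, 5, 9))
  res <- apply_support_filters(sup, params)
  expect_equal(res$tier1, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(res$tier2, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("tier-1 fusions equal the planted truth with exact flags", {
  cfg <- sim_config(seed = 43, n_genes = 30, n_lincrna_genes = 6,
                    n_true_fusions = 10, n_fails_coverage = 5,
                    n_fails_combined = 5, n_fails_distance = 5,
                    n_fails_support = 5, n_non_fusion = 30,
                    n_target_pairs = 2, n_near_decoys = 1, n_far_decoys = 1)
  ref <- simulate_reference(cfg)
  fus <- simulate_fusion_alignments(ref, cfg)
  det <- detect_candidates(fus$alignments)
  sup <- count_junction_support(det$candidates, fus$junctions)
  tiers <- apply_support_filters(sup)
  planted <- fus$truth$query_id[fus$truth$status == "true_fusion"]
  expect_setequal(tiers$query_id[tiers$tier1], planted)
  audit <- merge(det$audit, fus$truth, by = "query_id")
  expect_true(all(!audit$pass_locus_coverage[audit$status == "fails_coverage"]))
  expect_true(all(!audit$pass_combined_coverage[audit$status == "fails_combined"]))
  expect_true(all(!audit$pass_distance[audit$status == "fails_distance"]))
  # each failing read fails only its planted criterion
  fc <- audit[audit$status == "fails_coverage", ]
  expect_true(all(fc$pass_combined_coverage & fc$pass_distance))
})

test_that("parental gene assignment picks the maximal exonic overlap", {
  ann <- list(
    gene_model("G1", "protein_coding", list(
      transcript_model("G1.1", "G1", "chr1", "+", cbind(1000, 2000)))),
    gene_model("G2", "protein_coding", list(
      transcript_model("G2.1", "G2", "chr1", "+", cbind(1900, 3000)))),
    gene_model("G3", "protein_coding", list(
      transcript_model("G3.1", "G3", "chr2", "+", cbind(100, 600)))))
  cand <- list(query_id = "r", loci = data.frame(
    chrom = c("chr1", "chr2"), strand = "+",
    target_start = c(1500, 100), target_end = c(2000, 500),
    query_start = c(0, 500), query_end = c(500, 1000)))
  # locus 1 overlaps G1 by 500 bp and G2 by 100 bp
  expect_equal(assign_parental_genes(cand, ann), c("G1", "G3"))
  # a locus with no gene overlap gets a novel-locus label
  cand2 <- list(query_id = "r", loci = data.frame(
    chrom = "chr3", strand = "+", target_start = 5000000,
    target_end = 5001000, query_start = 0, query_end = 1000))
  expect_equal(assign_parental_genes(cand2, ann), "novel_locus:chr3:5000000")
})

test_that("database matching is unordered after symbol mapping", {
  map <- data.frame(symbol = c("A_symbol", "B_symbol", "C_symbol"),
                    gene_id = c("ENSG_A", "ENSG_B", "ENSG_C"))
  db <- data.frame(symbol_a = "B_symbol", symbol_b = "A_symbol")
  pairs <- data.frame(gene_a = c("ENSG_A", "ENSG_A"),
                      gene_b = c("ENSG_B", "ENSG_C"))
  res <- match_to_database(pairs, db, map)
  expect_equal(res$in_database, c(TRUE, FALSE))
  # unmapped database symbols are skipped with a warning
  db2 <- rbind(db, data.frame(symbol_a = "X_symbol", symbol_b = "A_symbol"))
  expect_warning(res2 <- match_to_database(pairs, db2, map), "unmapped")
  expect_equal(nrow(attr(res2, "unmapped")), 1L)
  # empty database: zero matches
  res3 <- match_to_database(pairs, db[0, ], map)
  expect_false(any(res3$in_database))
})
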