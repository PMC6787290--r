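test_that("each canonical two-transcript geometry yields its single event", {
  # skipped exon
  g_se <- make_gene("gSE", list(cbind(c(100, 300, 500), c(200, 400, 600)),
                                cbind(c(100, 500), c(200, 600))))
  ev <- enumerate_as_events(g_se)
  expect_equal(ev$event_type, "SE")
  expect_match(ev$event_id, "SE:chr1:\\+:200:300:400:500")
  expect_equal(ev$inclusion, "gSE.1")
  expect_equal(ev$exclusion, "gSE.2")
  # retained intron
  g_ri <- make_gene("gRI", list(cbind(c(100, 300), c(200, 400)),
                                cbind(100, 400)))
  ev <- enumerate_as_events(g_ri)
  expect_equal(ev$event_type, "RI")
  expect_equal(ev$inclusion, "gRI.2")   # the intron-retaining form
  # alternative 5' splice site (donor shift on the plus strand)
  g_a5 <- make_gene("gA5", list(cbind(c(100, 300), c(200, 400)),
                                cbind(c(100, 300), c(220, 400))))
  expect_equal(enumerate_as_events(g_a5)$event_type, "A5")
  # the same geometry on the minus strand is an A3
  g_a3m <- make_gene("gA3m", list(cbind(c(100, 300), c(200, 400)),
                                  cbind(c(100, 300), c(220, 400))),
                     strand = "-")
  expect_equal(enumerate_as_events(g_a3m)$event_type, "A3")
  # alternative 3' splice site (acceptor shift on the plus strand)
  g_a3 <- make_gene("gA3", list(cbind(c(100, 300), c(200, 400)),
                                cbind(c(100, 280), c(200, 400))))
  expect_equal(enumerate_as_events(g_a3)$event_type, "A3")
  # mutually exclusive exons
  g_mxe <- make_gene("gMXE", list(
    cbind(c(100, 300, 900), c(200, 400, 1000)),
    cbind(c(100, 500, 900), c(200, 600, 1000))))
  ev <- enumerate_as_events(g_mxe)
  expect_equal(ev$event_type, "MXE")
  # alternative first exon
  g_af <- make_gene("gAF", list(cbind(c(100, 900), c(200, 1000)),
                                cbind(c(400, 900), c(500, 1000))))
  expect_equal(enumerate_as_events(g_af)$event_type, "AF")
  # alternative last exon; on the minus strand it is the AF
  g_al <- make_gene("gAL", list(cbind(c(100, 500), c(200, 600)),
                                cbind(c(100, 800), c(200, 900))))
  expect_equal(enumerate_as_events(g_al)$event_type, "AL")
  g_afm <- make_gene("gAFm", list(cbind(c(100, 500), c(200, 600)),
                                  cbind(c(100, 800), c(200, 900))),
                     strand = "-")
  expect_equal(enumerate_as_events(g_afm)$event_type, "AF")
  # single-transcript gene: no events
  g1 <- make_gene("g1", list(cbind(c(100, 300), c(200, 400))))
  expect_equal(nrow(enumerate_as_events(g1)), 0L)
})

test_that("events deduplicate across transcript pairs", {
  # three transcripts: two share the inclusion form of one SE
  g <- make_gene("g", list(
    cbind(c(100, 300, 500), c(200, 400, 600)),
    cbind(c(120, 300, 500), c(200, 400, 610)),
    cbind(c(100, 500), c(200, 600))))
  ev <- enumerate_as_events(g)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$inclusion, "g.1,g.2")
  expect_equal(ev$exclusion, "g.3")
})

test_that("event enumeration matches the exhaustive brute-force oracle", {
  cfg <- sim_config(seed = 31, n_genes = 40, n_lincrna_genes = 8,
                    n_target_pairs = 2, n_near_decoys = 2, n_far_decoys = 2)
  ref <- simulate_reference(cfg)
  for (g in ref$genes) {
    got <- event_signatures(enumerate_as_events(g))
    expect_identical(got, oracle_as_events(g), info = g$gene_id)
  }
})

test_that("planted event types are recovered exactly per gene", {
  cfg <- sim_config(seed = 32, n_genes = 30, n_lincrna_genes = 8,
                    n_target_pairs = 2, n_near_decoys = 2, n_far_decoys = 2)
  ref <- simulate_reference(cfg)
  ev <- enumerate_as_events_all(ref$genes)
  planted <- ref$truth$planted_events
  expect_setequal(paste(ev$gene_id, ev$event_type),
                  paste(planted$gene_id, planted$event_type))
})

test_that("proportion test reproduces textbook chi-squared values", {
  # 2x2 table [[10,20],[20,10]] without continuity correction
  res <- event_type_proportions(list(s1 = c(SE = 10, RI = 20),
                                     s2 = c(SE = 20, RI = 10)))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(res$df, 1L)
  expect_true(all(abs(rowSums(res$percentages) - 100) < 1e-9))
  # identical count vectors give statistic 0, p = 1
  res0 <- event_type_proportions(list(s1 = c(SE = 5, A5 = 5),
                                      s2 = c(SE = 5, A5 = 5)))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)
  # zero-event samples are excluded with a warning
  expect_warning(
    event_type_proportions(list(s1 = c(SE = 5), s2 = c(SE = 8),
                                s3 = numeric(0))),
    "zero events")
})

test_that("divergence score follows the summed Jaccard definition", {
  b <- list(gene = c("k1", "k2"))
  # identical catalogs in all four cancer samples: D = 0
  expect_equal(divergence_score(b, rep(list(b), 4))$D, 0)
  # fully disjoint catalogs: every term is 1, D = 4
  disj <- list(gene = "k3")
  expect_equal(divergence_score(b, rep(list(disj), 4))$D, 4)
  # one half-overlapping comparison: D = 1 - 1/2 = 0.5
  half <- list(gene = "k1")
  res <- divergence_score(b, list(half, b, b, b))
  expect_equal(res$D, 0.5)
  # gene absent from both members contributes 0
  res2 <- divergence_score(list(g2 = "x"), list(list(g2 = "x", g3 = "y")))
  expect_equal(res2$D[res2$gene_id == "g2"], 0)
  expect_equal(res2$D[res2$gene_id == "g3"], 1)
})

test_that("divergence terms stay in [0,1] and match the oracle", {
  set.seed(77)
  keys <- paste0("k", 1:6)
  for (rep in 1:25) {
    n_cancer <- sample(1:5, 1)
    genes <- paste0("g", 1:4)
    rand_cat <- function() {
      cat <- lapply(genes, function(g) sample(keys, sample(0:4, 1)))
      names(cat) <- genes
      cat[lengths(cat) > 0]
    }
    normal <- rand_cat()
    cancers <- replicate(n_cancer, rand_cat(), simplify = FALSE)
    res <- divergence_score(normal, cancers)
    expect_true(all(res$D >= 0 & res$D <= n_cancer))
    for (i in seq_len(nrow(res)))
      expect_equal(res$D[i],
                   oracle_divergence(normal, cancers, res$gene_id[i]))
  }
})

test_that("rank_spliced_genes orders by D with lexicographic tie-break", {
  scores <- data.frame(gene_id = c("g1", "g2", "g3"), D = c(2, 0.5, 2))
  expect_equal(rank_spliced_genes(scores, n = 2), c("g1", "g3"))
  expect_equal(rank_spliced_genes(scores, n = 0), character(0))
  expect_warning(all4 <- rank_spliced_genes(scores, n = 10), "returning all")
  expect_equal(all4, c("g1", "g3", "g2"))
  expect_equal(rank_spliced_genes(data.frame(gene_id = "gA", D = 3.9), n = 1),
               "gA")
})
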