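# Promoter binding, DEG intersection with directionality, mark co-filtering,
# hypergeometric overlap and RPM.

test_that("promoter binding is any-overlap, strand-aware and multi-gene", {
  ann <- gene_annotation(c("g1", "g2", "g3"), "chr1", c("+", "+", "-"),
                         c(10000, 16000, 50000), c(11000, 17000, 51000))
  # peak covering g1's TSS
  expect_equal(assign_peaks_to_promoters(GRanges("chr1", IRanges(9900, 10100)),
                                         ann), "g1")
  # far from every promoter
  expect_equal(length(assign_peaks_to_promoters(
    GRanges("chr1", IRanges(200000, 200100)), ann)), 0L)
  # one peak spanning two adjacent promoters (g1 TSS 10000, g2 TSS 16000)
  both <- assign_peaks_to_promoters(GRanges("chr1", IRanges(12400, 13600)),
                                    ann, upstream = 2500, downstream = 2500)
  expect_setequal(both, c("g1", "g2"))
  # minus-strand promoter extends genomic-right of the TSS (51000)
  expect_equal(assign_peaks_to_promoters(GRanges("chr1", IRanges(53000, 53200)),
                                         ann), "g3")
})

test_that("bound x DEG intersection counts directions as specified", {
  de <- de_table(c("g1", "g2", "g3", "g4", "g5"),
                 log2fc = c(1, -2, 3, 1, 0),
                 pvalue = rep(0.001, 5),
                 fdr = c(1e-5, 1e-4, 1e-4, 0.5, 1e-6))
  res <- intersect_bound_degs(c("g1", "g2", "g3", "g5"), de, fdr_cut = 0.001)
  # g4 fails FDR; g5 has log2FC 0 (excluded from directions)
  expect_setequal(res$co_occurring, c("g1", "g2", "g3", "g5"))
  expect_equal(res$n_up, 2L)
  expect_equal(res$n_down, 1L)
  expect_equal(res$fraction_up, 2 / 3)
  expect_equal(res$binomial_p, oracle_binom_ge(2, 3))

  # empty intersection is flagged, not an error
  empty <- intersect_bound_degs("g4", de, fdr_cut = 1e-9)
  expect_true(empty$empty)
  expect_equal(empty$binomial_p, 1)

  # bound genes missing from the DE table are reported
  res2 <- intersect_bound_degs(c("g1", "missing"), de)
  expect_equal(res2$missing_genes, "missing")
})

test_that("exact binomial tail matches direct pmf summation up to n = 1000", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(c(3:50, 105, 500, 1000), 1)
    k <- sample.int(n, 1)
    de <- de_table(sprintf("g%04d", 1:n),
                   log2fc = c(rep(1, k), rep(-1, n - k)),
                   pvalue = rep(1e-4, n), fdr = rep(1e-4, n))
    res <- intersect_bound_degs(de$gene_id, de, fdr_cut = 0.001)
    expect_equal(res$binomial_p, oracle_binom_ge(k, n), tolerance = 1e-12)
  }
  # the 'extreme' alternative uses the larger direction count
  de <- de_table(c("a", "b", "c"), c(-1, -1, -1), rep(1e-4, 3), rep(1e-4, 3))
  res <- intersect_bound_degs(c("a", "b", "c"), de, fdr_cut = 0.001,
                              alternative = "extreme")
  expect_equal(res$binomial_p, oracle_binom_ge(3, 3))
})

test_that("differential mark filter applies the conjunction and scale invariance", {
  ann <- toy_annotation()
  base <- lapply(toy_lengths, function(L) rep(2, L))
  enr <- base
  enr$chrA[1501:3000] <- 8  # covers gA's promoter region
  tf_case <- coverage_track(enr); tf_ctrl <- coverage_track(base)
  mk_case <- coverage_track(enr); mk_ctrl <- coverage_track(base)
  regions <- GRanges("chrA", IRanges(c(1800, 5800), width = 400))
  de <- de_table(c("gA", "gB", "gC"), c(2, 0, 0), c(0.01, 0.5, 0.5),
                 c(0.05, 0.9, 0.9))
  res <- differential_mark_filter(tf_case, tf_ctrl, mk_case, mk_ctrl,
                                  regions, ann, de,
                                  promoter_window = c(500, 500))
  expect_true(all(c("gA", "gB") %in% res$table$gene_id))
  expect_equal(res$filtered$gene_id, "gA")
  expect_gt(res$filtered$tf_log2fc, 0.5)

  # null: identical tracks, nothing passes
  null <- differential_mark_filter(tf_ctrl, tf_ctrl, mk_ctrl, mk_ctrl,
                                   regions, ann, de,
                                   promoter_window = c(500, 500))
  expect_equal(nrow(null$filtered), 0L)
  expect_true(all(abs(null$table$tf_log2fc) < 1e-12))

  # multiplying one track by a constant changes nothing (normalisation)
  scaled <- coverage_track(lapply(enr, function(v) 7 * v))
  res2 <- differential_mark_filter(scaled, tf_ctrl, mk_case, mk_ctrl,
                                   regions, ann, de,
                                   promoter_window = c(500, 500))
  expect_equal(res2$table$tf_log2fc, res$table$tf_log2fc, tolerance = 1e-12)

  # p-value gate: good fold changes but weak DE evidence are filtered out
  de2 <- de_table(c("gA", "gB", "gC"), c(2, 0, 0), c(0.5, 0.5, 0.5),
                  c(0.9, 0.9, 0.9))
  res3 <- differential_mark_filter(tf_case, tf_ctrl, mk_case, mk_ctrl,
                                   regions, ann, de2,
                                   promoter_window = c(500, 500))
  expect_equal(nrow(res3$filtered), 0L)
})

test_that("hypergeometric overlap matches enumeration and its edge cases", {
  u <- sprintf("u%02d", 1:10)
  res <- hypergeometric_overlap(u[1:5], u[c(1:4)], u)
  expect_equal(res$overlap, 4L)
  expect_equal(res$pvalue, 5 / 210, tolerance = 1e-12)

  expect_equal(hypergeometric_overlap(u, u, u)$pvalue, 1)
  expect_equal(hypergeometric_overlap(u[1:3], u[4:6], u)$pvalue, 1)
  expect_error(hypergeometric_overlap(c(u[1], "zz"), u[1:2], u), "universe")

  set.seed(5)
  for (i in 1:30) {
    N <- sample(4:12, 1)
    uni <- sprintf("x%02d", 1:N)
    A <- sample(uni, sample.int(N, 1))
    B <- sample(uni, sample.int(N, 1))
    k <- length(intersect(A, B))
    expect_equal(hypergeometric_overlap(A, B, uni)$pvalue,
                 oracle_hyper_ge(k, N, length(A), length(B)),
                 tolerance = 1e-12)
  }
})

test_that("RPM is the documented arithmetic", {
  expect_equal(unname(rpm(500, 2e6)), 250)
  cts <- c(a = 10, b = 0, c = 90)
  expect_equal(sum(rpm(cts)), 1e6)
  expect_equal(unname(rpm(cts)["b"]), 0)
  expect_error(rpm(c(-1, 2), 10), "non-negative")
  expect_error(rpm(c(1, 2), 0), "total_mapped")
})
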