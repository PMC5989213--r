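# Composition, geography and Jaccard statistics against hand counts and
# naive oracles.

test_that("identical peak and genome composition gives chi2 = 0, p = 1", {
  g <- DNAStringSet(c(chr1 = "ATATATAT"))
  res <- at_composition_test(GRanges("chr1", IRanges(1, 8)), g)
  expect_equal(res$peak_at_fraction, 1)
  expect_equal(res$bg_at_fraction, 1)
  expect_equal(res$chi2, 0)
  expect_equal(res$pvalue, 1)
})

test_that("chi-squared equals the closed 2x2 formula and is label-swap invariant", {
  # peak bases: 80 AT / 20 GC; whole genome: 600 AT / 400 GC
  peak_seq <- paste0(strrep("AT", 40), strrep("GC", 10))
  rest <- paste0(strrep("TA", 260), strrep("CG", 190))
  g <- DNAStringSet(c(chr1 = paste0(peak_seq, rest)))
  pk <- GRanges("chr1", IRanges(1, 100))
  res <- at_composition_test(pk, g)
  expect_equal(res$peak_at, 80)
  expect_equal(res$bg_at, 600)
  expect_equal(res$chi2, oracle_chi2(80, 20, 600, 400), tolerance = 1e-12)
  expect_equal(res$chi2, 15.40616, tolerance = 1e-5)

  # swapping A/T and G/C labels (complementing twice through a swap) leaves p
  swapped <- setNames(chartr("ATGC", "GCAT", as.character(g)), "chr1")
  res2 <- at_composition_test(pk, DNAStringSet(swapped))
  expect_equal(res2$pvalue, res$pvalue, tolerance = 1e-12)
  expect_equal(res2$chi2, res$chi2, tolerance = 1e-12)

  expect_error(at_composition_test(GRanges(), g), "empty")
  expect_error(at_composition_test(pk, DNAStringSet(c(chr1 = strrep("N", 200)))),
               "non-N")
})

test_that("peak-excluded background shifts the comparison", {
  peak_seq <- paste0(strrep("AT", 40), strrep("GC", 10))
  rest <- paste0(strrep("TA", 260), strrep("CG", 190))
  g <- DNAStringSet(c(chr1 = paste0(peak_seq, rest)))
  pk <- GRanges("chr1", IRanges(1, 100))
  res <- at_composition_test(pk, g, exclude_peaks_from_background = TRUE)
  expect_equal(res$bg_at, 520)
  expect_equal(res$bg_gc, 380)
})

test_that("TSS distance profile matches hand counts and is threshold-monotone", {
  ann <- gene_annotation("g1", "chr1", "+", 200000, 201000)
  mk <- function(mids) GRanges("chr1", IRanges(mids - 10, mids + 10))
  # distances -10 kb, +10 kb, +70 kb from the TSS at 200000
  pk <- mk(c(190000, 210000, 270000))
  prof <- tss_distance_profile(pk, ann, window_bp = 1e5, bin_bp = 1e4)
  expect_equal(prof$fraction_within_50kb, 2 / 3)
  expect_equal(sum(prof$density), 1)

  at_tss <- mk(c(200000, 200000))
  p2 <- tss_distance_profile(at_tss, ann, window_bp = 1e4, bin_bp = 1e3)
  expect_equal(p2$fraction_within_50kb, 1)
  zero_bin <- which(p2$breaks[-length(p2$breaks)] <= 0 & p2$breaks[-1] > 0)
  expect_equal(p2$counts[zero_bin], 2L)

  p3 <- tss_distance_profile(mk(260000), ann, window_bp = 1e5, bin_bp = 1e4)
  expect_equal(p3$fraction_within_50kb, 0)

  # monotone in the threshold
  d <- abs(prof$distances)
  fr <- vapply(c(1e3, 1e4, 5e4, 1e5), function(t) mean(d <= t), 0)
  expect_true(all(diff(fr) >= 0))
  expect_error(tss_distance_profile(pk, ann, window_bp = 10, bin_bp = 100),
               "window_bp")
})

test_that("signed TSS distance is strand-oriented", {
  ann <- gene_annotation(c("gp", "gm"), c("chr1", "chr2"), c("+", "-"),
                         c(5000, 5000), c(6000, 6000))
  # midpoint 500 bp left of the + TSS (5000): upstream, negative
  pk_p <- GRanges("chr1", IRanges(4490, 4509))
  # midpoint 500 bp right of the - TSS (6000): upstream in gene orientation
  pk_m <- GRanges("chr2", IRanges(6490, 6509))
  dp <- tss_distance_profile(pk_p, ann, 1e4, 1e3)$distances
  dm <- tss_distance_profile(pk_m, ann, 1e4, 1e3)$distances
  expect_lt(dp, 0)
  expect_lt(dm, 0)
})

test_that("region classification follows the precedence and conserves counts", {
  ann <- gene_annotation("g1", "chr1", "+", 10000, 20000)
  exons <- GRanges("chr1", IRanges(15000, 15500))
  enh <- GRanges("chr1", IRanges(40000, 41000))
  pk <- GRanges("chr1", IRanges(c(9500, 15100, 17000, 40400, 70000),
                                width = 100))
  cls <- classify_regions(pk, ann, exons = exons, enhancers = enh)
  expect_equal(as.vector(cls), c(1L, 1L, 1L, 1L, 1L))
  expect_equal(attr(cls, "assignment"),
               c("promoter", "exon", "intron", "enhancer", "intergenic"))
  expect_equal(sum(cls), length(pk))
  # without enhancer annotation the enhancer peak collapses to intergenic
  cls2 <- classify_regions(pk, ann, exons = exons)
  expect_equal(unname(cls2["enhancer"]), 0L)
  expect_equal(unname(cls2["intergenic"]), 2L)
  expect_equal(sum(cls2), length(pk))
})

test_that("Jaccard matches hand arithmetic and the per-base oracle", {
  A <- GRanges("chr1", IRanges(1, 100))
  expect_equal(jaccard_index(A, A)$jaccard, 1)
  B <- GRanges("chr1", IRanges(51, 150))
  j <- jaccard_index(A, B)
  expect_equal(j$intersection_bp, 50)
  expect_equal(j$union_bp, 150)
  expect_equal(j$jaccard, 1 / 3)
  C <- GRanges("chr2", IRanges(1, 10))
  expect_equal(jaccard_index(A, C)$jaccard, 0)
  expect_error(jaccard_index(A, GRanges()), "non-empty")

  set.seed(99)
  lens <- c(c1 = 60L, c2 = 45L)
  for (i in 1:40) {
    X <- random_intervals(lens, sample(2:6, 1))
    Y <- random_intervals(lens, sample(2:6, 1))
    expect_equal(jaccard_index(X, Y)$jaccard, oracle_jaccard(X, Y))
    expect_equal(jaccard_index(X, Y)$jaccard, jaccard_index(Y, X)$jaccard)
  }
})

test_that("permutation fast path agrees with the GRanges Jaccard", {
  set.seed(7)
  lens <- c(c1 = 80L, c2 = 60L)
  for (i in 1:25) {
    X <- reduce(random_intervals(lens, 4))
    Y <- reduce(random_intervals(lens, 4))
    inter <- 0
    for (ch in names(lens)) {
      xs <- X[seqnames(X) == ch]; ys <- Y[seqnames(Y) == ch]
      inter <- inter + epihub:::.inter_bp(start(xs), end(xs), start(ys), end(ys))
    }
    expect_equal(inter, jaccard_index(X, Y)$intersection_bp)
  }
})

test_that("permutation p is calibrated in the obvious extremes", {
  lens <- c(c1 = 1000L)
  A <- GRanges("c1", IRanges(1, 50))
  res_self <- jaccard_with_permutation(A, A, lens, n_permutations = 99, seed = 1)
  # observed J = 1 can only be tied, never beaten
  expect_equal(res_self$jaccard, 1)
  expect_lt(res_self$permutation_p, 0.2)
  B <- GRanges("c1", IRanges(500, 549))
  res <- jaccard_with_permutation(A, B, lens, n_permutations = 99, seed = 1)
  expect_equal(res$jaccard, 0)
  expect_equal(res$permutation_p, 1)  # every permutation has J* >= 0
})
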