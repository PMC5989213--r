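# Generator contracts: determinism, degenerate parameter behaviour, and
# convergence of empirical statistics to their parameters.

test_that("every generator is bit-for-bit reproducible given a seed", {
  a <- simulate_genome(n_chrom = 1, chrom_length = 2e4, n_genes = 8,
                       gene_length = 400, seed = 3)
  b <- simulate_genome(n_chrom = 1, chrom_length = 2e4, n_genes = 8,
                       gene_length = 400, seed = 3)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$annotation, b$annotation)

  pa <- simulate_peaks(a$genome, a$annotation, n_peaks = 10, peak_length = 50,
                       seed = 5)
  pb <- simulate_peaks(b$genome, b$annotation, n_peaks = 10, peak_length = 50,
                       seed = 5)
  expect_identical(as.character(pa$genome), as.character(pb$genome))
  expect_identical(pa$peaks, pb$peaks)
  expect_identical(pa$truth$bound_genes, pb$truth$bound_genes)

  ca <- simulate_coverage(a$genome, a$annotation, pa$truth, depth = 3, seed = 5)
  cb <- simulate_coverage(b$genome, b$annotation, pb$truth, depth = 3, seed = 5)
  expect_identical(lapply(ca$case$cov, as.numeric),
                   lapply(cb$case$cov, as.numeric))

  ea <- simulate_expression(a$annotation, ca$truth, seed = 5)
  eb <- simulate_expression(b$annotation, cb$truth, seed = 5)
  expect_identical(ea$counts, eb$counts)
  # changing the seed changes the draw
  expect_false(identical(ea$counts,
                         simulate_expression(a$annotation, ca$truth, seed = 6)$counts))
})

test_that("degenerate base composition and gene-count contracts hold", {
  g <- simulate_genome(n_chrom = 1, chrom_length = 5000, base_at_fraction = 0.999999,
                       n_genes = 5, gene_length = 100, seed = 1)
  freq <- Biostrings::letterFrequency(g$genome, c("A", "T", "G", "C"))
  expect_equal(sum(freq[, c("G", "C")]), 0)
  expect_equal(nrow(g$annotation), 5L)
  expect_error(simulate_genome(n_chrom = 1, chrom_length = 1000, n_genes = 20,
                               gene_length = 100, seed = 1),
               "cannot place")
  expect_error(simulate_genome(base_at_fraction = 1), "\\(0, 1\\)")
})

test_that("empirical A/T fraction converges to base_at_fraction", {
  g <- simulate_genome(n_chrom = 1, chrom_length = 1e6, base_at_fraction = 0.59,
                       n_genes = 10, gene_length = 100, seed = 2)
  at <- sum(Biostrings::letterFrequency(g$genome, "AT")) / 1e6
  expect_lt(abs(at - 0.59), 0.005)  # ~10 binomial SEs
})

test_that("genes never overlap and TSS follows strand", {
  g <- simulate_genome(n_chrom = 2, chrom_length = 5e4, n_genes = 40,
                       gene_length = 600, seed = 9)
  ann <- g$annotation
  for (ch in unique(ann$chrom)) {
    a <- ann[ann$chrom == ch, ]
    a <- a[order(a$start), ]
    if (nrow(a) > 1) expect_true(all(a$start[-1] > a$end[-nrow(a)]))
  }
  expect_equal(ann$tss, ifelse(ann$strand == "+", ann$start, ann$end))
})

test_that("promoter peaks sit on TSSs and carry the planted motif", {
  g <- simulate_genome(n_chrom = 1, chrom_length = 1e5, n_genes = 10,
                       gene_length = 1000, seed = 4)
  pk <- simulate_peaks(g$genome, g$annotation, n_peaks = 10, peak_length = 200,
                       promoter_fraction = 1, motif = "AAAATAA", seed = 4)
  mids <- floor((start(pk$peaks) + end(pk$peaks)) / 2)
  expect_true(all(abs(sort(mids) - sort(g$annotation$tss)) <= 1))
  seqs <- interval_seqs(pk$genome, pk$peaks)
  expect_true(all(vcountPattern("AAAATAA", seqs) >= 1))
  expect_setequal(pk$truth$bound_genes, g$annotation$gene_id)
  expect_error(simulate_peaks(g$genome, g$annotation, peak_length = 5,
                              motif = "AAAATAW"), "shorter than the motif")
})

test_that("flat coverage matches its Poisson depth and truth records the scale", {
  g <- simulate_genome(n_chrom = 1, chrom_length = 1e5, n_genes = 5,
                       gene_length = 200, seed = 8)
  truth <- list(bound_genes = character(0))
  cv <- simulate_coverage(g$genome, g$annotation, truth, depth = 100,
                          enrichment = 1, condition_scale = 1, seed = 8)
  m <- mean(as.numeric(cv$empty$cov$chr1))
  expect_lt(abs(m - 100), 1)  # Poisson SE(mean) ~ 0.03
  expect_true(all(cv$truth$accessibility_effect == 1))

  truth2 <- list(bound_genes = g$annotation$gene_id[1])
  cv2 <- simulate_coverage(g$genome, g$annotation, truth2, depth = 10,
                           enrichment = 4, condition_scale = 3,
                           promoter_halfwidth = 500, seed = 8)
  eff <- cv2$truth$accessibility_effect
  expect_equal(unname(eff[g$annotation$gene_id[1]]), 3)
  expect_true(all(eff[-1] == 1))
  tss <- g$annotation$tss[1]
  win_case <- mean(as.numeric(window(cv2$case$cov$chr1, tss - 400, tss + 400)))
  win_empty <- mean(as.numeric(window(cv2$empty$cov$chr1, tss - 400, tss + 400)))
  expect_gt(win_case / win_empty, 2)   # planted ratio 3, Poisson noise
})

test_that("true log2 fold changes follow the coupling model", {
  g <- simulate_genome(n_chrom = 1, chrom_length = 2e5, n_genes = 100,
                       gene_length = 500, seed = 6)
  bound <- g$annotation$gene_id[1:40]
  truth <- list(bound_genes = bound,
                accessibility_effect = setNames(
                  ifelse(g$annotation$gene_id %in% bound, 4, 1),
                  g$annotation$gene_id))
  ex0 <- simulate_expression(g$annotation, truth, coupling = 0,
                             sigma_noise = 0, seed = 6)
  expect_true(all(ex0$truth$true_log2fc == 0))

  ex1 <- simulate_expression(g$annotation, truth, coupling = 1,
                             sigma_noise = 0.25, seed = 6)
  expect_lt(abs(mean(ex1$truth$true_log2fc[bound]) - 2), 3 * 0.25 / sqrt(40))
  expect_lt(abs(mean(ex1$truth$true_log2fc[setdiff(g$annotation$gene_id, bound)])),
            3 * 0.25 / sqrt(60))
  expect_error(simulate_expression(g$annotation, truth, n_replicates = 1),
               "n_replicates")
})
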