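# Shared fixtures and independent oracles. Oracles are deliberately naive
# (per-base sets, direct summation, exhaustive enumeration) and never call
# the code paths they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
  library(S4Vectors)
})

tiny_genome <- function() {
  DNAStringSet(c(chrA = "ACGTACGTACGTACGTACGTACGTACGTACGT",
                 chrB = "TTTTAAAACCCCGGGGTTTTAAAACCCCGGGG"))
}

# annotation with well-separated genes on a 10 kb two-chromosome genome
toy_annotation <- function() {
  gene_annotation(gene_id = c("gA", "gB", "gC"),
                  chrom = c("chrA", "chrA", "chrB"),
                  strand = c("+", "-", "+"),
                  start = c(2001, 6001, 3001),
                  end = c(2500, 6500, 3500))
}

toy_lengths <- c(chrA = 10000L, chrB = 10000L)

# uniform coverage track of the given depth on toy_lengths
flat_track <- function(depth = 2, lens = toy_lengths) {
  coverage_track(lapply(lens, function(L) Rle(depth, L)))
}

# --- oracles ----------------------------------------------------------------

# Jaccard by explicit per-base membership sets
oracle_jaccard <- function(A, B) {
  base_set <- function(gr) {
    unlist(lapply(seq_along(gr), function(i)
      paste0(as.character(seqnames(gr)[i]), ":",
             seq(start(gr)[i], end(gr)[i]))))
  }
  a <- unique(base_set(A)); b <- unique(base_set(B))
  length(intersect(a, b)) / length(union(a, b))
}

# 2x2 Pearson chi-squared, closed form N(ad-bc)^2 / row/col products
oracle_chi2 <- function(a, b, c, d) {
  N <- a + b + c + d
  N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Pearson r by direct summation
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    (sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2))
}

# one-sided exact binomial tail P(X >= k), direct pmf summation
oracle_binom_ge <- function(k, n, p = 0.5) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), 0))
}

# hypergeometric upper tail P(X >= k) by exhaustive enumeration of draws
oracle_hyper_ge <- function(k, N, K, n) {
  tot <- choose(N, n)
  sum(vapply(max(k, 0):min(K, n), function(i)
    choose(K, i) * choose(N - K, n - i), 0)) / tot
}

# random small interval set on a toy genome
random_intervals <- function(lens, n) {
  ch <- sample(names(lens), n, replace = TRUE)
  w <- sample.int(8, n, replace = TRUE)
  s <- vapply(ch, function(c_) sample.int(lens[[c_]] - 8L, 1L), 0L)
  GRanges(ch, IRanges(s, width = w))
}

# one miniature ground-truthed dataset, built once and reused
small_config <- function(seed = 11) {
  pipeline_config(seed = seed, n_chrom = 2, chrom_length = 1e5,
                  n_genes = 10, gene_length = 500, n_peaks = 30,
                  peak_length = 200, promoter_fraction = 0.5,
                  depth = 5, enrichment = 5, condition_scale = 4,
                  promoter_halfwidth = 500,
                  jaccard_permutations = 100, kmer_shuffles = 4)
}

.fixture_env <- new.env(parent = emptyenv())
small_dataset <- function() {
  if (is.null(.fixture_env$ds))
    .fixture_env$ds <- simulate_dataset(small_config())
  .fixture_env$ds
}
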