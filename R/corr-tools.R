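# Accessibility-expression correlation under iterative |log2FC| thresholding,
# and genome-wide binned track correlation.

#' Per-gene case/control coverage ratio over a TSS-anchored window
#'
#' For each gene, sums the depth-normalised signal (per million coverage
#' units, as in [tss_profile()]) over the oriented window
#' `[-before, +after)` around the TSS in each condition, and forms
#' `(case + pseudocount) / (control + pseudocount)`. Genes whose window is
#' truncated at a chromosome edge get `NA`.
#'
#' @param case,control [coverage_track()]s on the same genome, both with
#'   positive totals.
#' @param annotation A [gene_annotation()].
#' @param before,after Window extent in bp (defaults 1500 and 5000).
#' @param pseudocount Added to both normalised sums (default 1).
#' @return A `data.frame` with columns `gene_id`, `case_signal`,
#'   `control_signal` (normalised window sums), `mean_case`, `mean_control`
#'   (per-base means), `ratio` and `log2_ratio`.
#' @export
region_condition_ratio <- function(case, control, annotation, before = 1500,
                                   after = 5000, pseudocount = 1) {
  if (case$total <= 0 || control$total <= 0)
    .stopf("both tracks must have positive total coverage")
  if (!identical(chrom_lengths(case), chrom_lengths(control)))
    .stopf("case and control tracks are on different genomes")
  lens <- chrom_lengths(case)
  width <- before + after
  win_sum <- function(track, i) {
    ch <- annotation$chrom[i]
    tss <- annotation$tss[i]
    minus <- annotation$strand[i] == "-"
    lo <- if (minus) tss - (after - 1L) else tss - before
    hi <- if (minus) tss + before else tss + (after - 1L)
    if (lo < 1L || hi > lens[[ch]]) return(NA_real_)
    .track_window_sum(track, ch, lo, hi)
  }
  n <- nrow(annotation)
  cs <- vapply(seq_len(n), function(i) win_sum(case, i), 0)
  ct <- vapply(seq_len(n), function(i) win_sum(control, i), 0)
  cs <- cs / (case$total / 1e6)
  ct <- ct / (control$total / 1e6)
  ratio <- (cs + pseudocount) / (ct + pseudocount)
  data.frame(gene_id = annotation$gene_id,
             case_signal = cs, control_signal = ct,
             mean_case = cs / width, mean_control = ct / width,
             ratio = ratio, log2_ratio = log2(ratio),
             stringsAsFactors = FALSE)
}

#' Iterative-threshold accessibility-expression correlation
#'
#' Starting from `start`, the |log2FC| filter is tightened by `step` for
#' `cycles` iterations; at each iteration the Pearson correlation between the
#' per-gene accessibility measure (log2 ratio by default) and the expression
#' log2 fold change is computed over the genes surviving the filter.
#' Correlations are reported as missing when fewer than 3 genes survive.
#'
#' @param ratios Output of [region_condition_ratio()] (or any data.frame with
#'   `gene_id` and `log2_ratio`/`ratio`).
#' @param de A [de_table()].
#' @param cycles Number of iterations (default 50).
#' @param start,step First threshold and per-cycle increment (defaults 0 and
#'   0.1).
#' @param log_ratio Correlate `log2(ratio)` (default) rather than the raw
#'   ratio.
#' @param signed Filter on signed `log2FC >= threshold` instead of
#'   `|log2FC| >= threshold`.
#' @return A `data.frame` of class `threshold_correlation` with columns
#'   `threshold`, `n_genes`, `pearson_r`, `pvalue`.
#' @export
iterative_threshold_correlation <- function(ratios, de, cycles = 50,
                                            start = 0, step = 0.1,
                                            log_ratio = TRUE, signed = FALSE) {
  m <- merge(ratios, as.data.frame(de)[, c("gene_id", "log2fc")],
             by = "gene_id")
  m <- m[is.finite(m$log2_ratio) & is.finite(m$log2fc), , drop = FALSE]
  if (!nrow(m)) .stopf("no shared genes between ratio table and DE table")
  x_all <- if (log_ratio) m$log2_ratio else m$ratio
  y_all <- m$log2fc
  thr <- start + step * (seq_len(cycles) - 1L)
  rows <- lapply(thr, function(t) {
    keep <- if (signed) y_all >= t else abs(y_all) >= t
    n <- sum(keep)
    if (n < 3)
      return(data.frame(threshold = t, n_genes = n,
                        pearson_r = NA_real_, pvalue = NA_real_))
    ct <- suppressWarnings(cor.test(x_all[keep], y_all[keep],
                                    method = "pearson"))
    data.frame(threshold = t, n_genes = n,
               pearson_r = unname(ct$estimate), pvalue = ct$p.value)
  })
  out <- do.call(rbind, rows)
  attr(out, "params") <- list(cycles = cycles, start = start, step = step,
                              log_ratio = log_ratio, signed = signed)
  class(out) <- c("threshold_correlation", "data.frame")
  out
}

#' @export
print.threshold_correlation <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("threshold correlation: %d cycles from %g by %g; first-row r = %.3f (n = %d)\n",
              p$cycles, p$start, p$step, x$pearson_r[1], x$n_genes[1]))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Genome-wide binned track correlation
#'
#' Sums both tracks in fixed-width bins across all chromosomes (terminal
#' ragged bins included), pairs the bins and computes the Pearson
#' correlation. Bins with zero signal in both tracks are retained by default
#' (they are informative agreement).
#'
#' @param trackA,trackB [coverage_track()]s on the same genome.
#' @param bin_bp Bin width in bp (default 1000).
#' @param drop_empty Drop bins with zero signal in both tracks.
#' @return An object of class `binned_correlation` with `pearson_r`,
#'   `n_bins`, `bin_bp` and the paired bin sums `x`, `y` (for XY plots).
#' @export
binned_track_correlation <- function(trackA, trackB, bin_bp = 1000,
                                     drop_empty = FALSE) {
  if (!identical(chrom_lengths(trackA), chrom_lengths(trackB)))
    .stopf("tracks are on different genomes")
  lens <- chrom_lengths(trackA)
  bin_sums <- function(track) {
    unlist(lapply(names(lens), function(ch) {
      L <- lens[[ch]]
      starts <- seq(1L, L, by = bin_bp)
      ends <- pmin(starts + bin_bp - 1L, L)
      viewSums(Views(track$cov[[ch]], starts, ends))
    }), use.names = FALSE)
  }
  x <- bin_sums(trackA)
  y <- bin_sums(trackB)
  if (drop_empty) {
    keep <- x > 0 | y > 0
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 3) .stopf("fewer than 3 bins; decrease bin_bp")
  structure(list(pearson_r = cor(x, y), n_bins = length(x),
                 bin_bp = bin_bp, x = x, y = y),
            class = "binned_correlation")
}

#' @export
print.binned_correlation <- function(x, ...) {
  cat(sprintf("binned track correlation: r = %.4f over %d bins of %d bp\n",
              x$pearson_r, x$n_bins, x$bin_bp))
  invisible(x)
}
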