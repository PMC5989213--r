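# TSS-anchored coverage profiling: single-nucleotide matrices normalised by
# total track coverage, fixed-width binning, intensity-sorted heatmap order
# and gene-set aggregate (metagene) profiles.

#' TSS-anchored coverage matrix
#'
#' Row `g`, column `j` holds the track value at `TSS_g + j` (plus strand) or
#' `TSS_g - j` (minus strand) for `j` in `[-before, after)`, divided by the
#' track total over 1e6 (signal per million coverage units), so the absolute
#' sequencing depth cancels. Windows truncated at chromosome edges are filled
#' with `NA` at the missing positions and flagged incomplete; aggregates use
#' complete rows only. Set `oriented = FALSE` for unoriented genomic
#' left-to-right windows.
#'
#' @param track A [coverage_track()] with positive total.
#' @param annotation A non-empty [gene_annotation()].
#' @param before,after Window extent upstream/downstream of the TSS in bp
#'   (defaults 2000 and 10000).
#' @param oriented Orient windows 5' to 3' by gene strand (default `TRUE`).
#' @return An object of class `profile_matrix`: `values` (genes x positions
#'   matrix), `offsets` (column offsets relative to the TSS), `bin_size`
#'   (1 for a per-base matrix), `complete` (logical per gene) and
#'   `normalization_constant`.
#' @export
tss_profile <- function(track, annotation, before = 2000, after = 10000,
                        oriented = TRUE) {
  if (track$total <= 0) .stopf("track has zero total coverage")
  if (!nrow(annotation)) .stopf("empty annotation")
  lens <- chrom_lengths(track)
  norm <- track$total / 1e6
  width <- before + after
  vals <- matrix(NA_real_, nrow = nrow(annotation), ncol = width,
                 dimnames = list(annotation$gene_id, NULL))
  for (i in seq_len(nrow(annotation))) {
    ch <- annotation$chrom[i]
    tss <- annotation$tss[i]
    minus <- oriented && annotation$strand[i] == "-"
    # genomic span covered by the oriented window
    lo <- if (minus) tss - (after - 1L) else tss - before
    hi <- if (minus) tss + before else tss + (after - 1L)
    clo <- max(lo, 1L); chi_ <- min(hi, lens[[ch]])
    if (clo > chi_) next
    v <- .track_window(track, ch, clo, chi_)
    row <- rep(NA_real_, width)
    # map genomic positions back to window offsets
    if (minus) {
      idx <- (tss + before) - (chi_:clo) + 1L
      row[idx] <- rev(v)
    } else {
      idx <- (clo:chi_) - (tss - before) + 1L
      row[idx] <- v
    }
    vals[i, ] <- row / norm
  }
  structure(list(values = vals, offsets = seq(-before, after - 1L),
                 before = before, after = after, bin_size = 1L,
                 complete = !apply(vals, 1, anyNA),
                 normalization_constant = track$total,
                 oriented = oriented),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d genes x %d %s (window -%d..+%d bp, %d complete rows)\n",
              nrow(x$values), ncol(x$values),
              if (x$bin_size == 1) "positions" else sprintf("bins of %d bp", x$bin_size),
              x$before, x$after, sum(x$complete)))
  invisible(x)
}

#' Bin a profile matrix and derive the heatmap row order
#'
#' Bin values are sums of the per-base values in each bin (the terminal bin
#' may be ragged); rows are ordered by decreasing total signal over the whole
#' window, ties broken by gene id ascending. The matrix keeps its input row
#' order; the heatmap order is returned in `$row_order`.
#'
#' @param pm A per-base `profile_matrix`.
#' @param bin_size Bin width in bp (default 200).
#' @return A binned `profile_matrix` with additional elements `row_order`
#'   (indices) and `row_totals`.
#' @export
bin_profile <- function(pm, bin_size = 200) {
  if (bin_size <= 0) .stopf("bin_size must be > 0")
  if (pm$bin_size != 1) .stopf("profile matrix is already binned")
  width <- ncol(pm$values)
  grp <- (seq_len(width) - 1L) %/% bin_size
  nb <- max(grp) + 1L
  binned <- t(rowsum(t(pm$values), grp))
  dimnames(binned) <- list(rownames(pm$values), NULL)
  totals <- rowSums(binned)
  ord <- order(-totals, rownames(binned))
  out <- pm
  out$values <- binned
  out$bin_size <- as.integer(bin_size)
  out$offsets <- -pm$before + bin_size * (seq_len(nb) - 1L)
  out$complete <- !apply(binned, 1, anyNA)
  out$row_order <- ord
  out$row_totals <- totals
  out
}

#' Aggregate (metagene) profile of a gene set
#'
#' Per-bin sum over all complete rows divided by the number of complete rows
#' (i.e. the gene-set mean profile); truncated rows are excluded.
#'
#' @param pm A `profile_matrix` (typically binned).
#' @return A numeric vector, one value per column, with the window offsets as
#'   names and the number of genes used in attribute `"n_genes"`.
#' @export
aggregate_profile <- function(pm) {
  keep <- pm$complete
  if (!any(keep)) .stopf("all profile rows are truncated; nothing to aggregate")
  m <- pm$values[keep, , drop = FALSE]
  agg <- colSums(m) / nrow(m)
  names(agg) <- pm$offsets
  attr(agg, "n_genes") <- nrow(m)
  agg
}
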