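# ChIP x RNA integration: promoter-binding assignment, bound-by-DEG
# intersection with a directionality test, differential-mark co-filtering,
# hypergeometric set overlap, and RPM normalisation.

#' Assign peaks to promoters
#'
#' A gene is called bound when any peak overlaps its strand-aware promoter
#' window (TSS - upstream to TSS + downstream, mirrored on minus-strand
#' genes) by at least 1 bp. One peak may bind several genes.
#'
#' @param peaks A `GRanges`.
#' @param annotation A [gene_annotation()].
#' @param upstream,downstream Promoter window extents in bp (defaults 2500
#'   and 2500).
#' @return A sorted character vector of bound gene ids.
#' @export
assign_peaks_to_promoters <- function(peaks, annotation, upstream = 2500,
                                      downstream = 2500) {
  prom <- promoter_ranges(annotation, upstream, downstream)
  hits <- findOverlaps(prom, peaks, ignore.strand = TRUE)
  sort(unique(mcols(prom)$gene_id[queryHits(hits)]))
}

#' Intersect promoter-bound genes with differentially expressed genes
#'
#' Intersects the bound set with the genes passing the FDR cut and tests the
#' direction balance among the co-occurring genes with a one-sided exact
#' binomial test against 0.5. Genes with log2FC exactly 0 are excluded from
#' both direction counts (direction undefined). The default alternative
#' tests enrichment of upregulation, `P(X >= n_up)`; `"extreme"` uses
#' `P(X >= max(n_up, n_down))`.
#'
#' @param bound Character vector of bound gene ids.
#' @param de A [de_table()].
#' @param fdr_cut FDR threshold defining DEGs (default 0.001).
#' @param alternative `"up"` (default) or `"extreme"`.
#' @return An object of class `intersection_result` with `bound_genes`,
#'   `deg_genes`, `co_occurring`, `n_up`, `n_down`, `fraction_up`,
#'   `binomial_p`, `missing_genes` (bound ids absent from the DE table) and
#'   an `empty` flag.
#' @export
intersect_bound_degs <- function(bound, de, fdr_cut = 0.001,
                                 alternative = c("up", "extreme")) {
  alternative <- match.arg(alternative)
  if (!nrow(de)) .stopf("empty DE table")
  bound <- unique(as.character(bound))
  missing <- setdiff(bound, de$gene_id)
  degs <- de$gene_id[!is.na(de$fdr) & de$fdr < fdr_cut]
  co <- intersect(bound, degs)
  lfc <- de$log2fc[match(co, de$gene_id)]
  n_up <- sum(lfc > 0)
  n_down <- sum(lfc < 0)
  n <- n_up + n_down
  if (n == 0) {
    p <- 1
  } else {
    k <- if (alternative == "up") n_up else max(n_up, n_down)
    p <- pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  }
  structure(list(bound_genes = bound, deg_genes = sort(degs),
                 co_occurring = sort(co), n_up = n_up, n_down = n_down,
                 fraction_up = if (n) n_up / n else NA_real_,
                 binomial_p = p, alternative = alternative,
                 fdr_cut = fdr_cut, missing_genes = sort(missing),
                 empty = n == 0),
            class = "intersection_result")
}

#' @export
print.intersection_result <- function(x, ...) {
  cat(sprintf("%d bound genes x %d DEGs (FDR < %g) -> %d co-occurring\n",
              length(x$bound_genes), length(x$deg_genes), x$fdr_cut,
              length(x$co_occurring)))
  if (!x$empty)
    cat(sprintf("  %d up / %d down (%.1f%% up), one-sided binomial p = %.3g\n",
                x$n_up, x$n_down, 100 * x$fraction_up, x$binomial_p))
  else
    cat("  empty intersection (binomial_p = 1)\n")
  if (length(x$missing_genes))
    cat(sprintf("  %d bound gene(s) missing from the DE table\n",
                length(x$missing_genes)))
  invisible(x)
}

#' Differential transcription-factor / histone-mark co-filter
#'
#' For each region, computes the depth-normalised coverage log2 fold change
#' (case/control, with a pseudocount on the per-million scale) for the
#' transcription-factor assay and for the histone-mark assay, maps regions
#' to genes via their promoter windows, attaches the differential-expression
#' p-value, and retains rows with both coverage log2FCs above `fc_cut` and
#' expression p below `p_cut`. The full unfiltered table is returned too,
#' for fold-change-vs-fold-change scatter plots.
#'
#' @param tf_case,tf_ctrl,mark_case,mark_ctrl [coverage_track()]s with
#'   positive totals on one genome.
#' @param regions A `GRanges` of candidate regions.
#' @param annotation A [gene_annotation()].
#' @param de A [de_table()].
#' @param fc_cut Coverage log2FC threshold (default 0.5).
#' @param p_cut Expression p-value threshold (default 0.05).
#' @param pseudocount Added to normalised sums (default 1).
#' @param promoter_window `c(upstream, downstream)` for region-to-gene
#'   mapping (default 2500/2500).
#' @return A list with `table` (one row per region x gene, columns
#'   `region`, `gene_id`, `tf_log2fc`, `mark_log2fc`, `de_p`, `pass`) and
#'   `filtered` (the passing subset).
#' @export
differential_mark_filter <- function(tf_case, tf_ctrl, mark_case, mark_ctrl,
                                     regions, annotation, de, fc_cut = 0.5,
                                     p_cut = 0.05, pseudocount = 1,
                                     promoter_window = c(2500, 2500)) {
  tracks <- list(tf_case, tf_ctrl, mark_case, mark_ctrl)
  if (any(vapply(tracks, function(t) t$total <= 0, TRUE)))
    .stopf("all four tracks must have positive total coverage")
  lens <- chrom_lengths(tf_case)
  .validate_intervals(as.character(seqnames(regions)), start(regions),
                      end(regions), lens, "region")
  norm_sum <- function(track, i) {
    .track_window_sum(track, as.character(seqnames(regions)[i]),
                      start(regions)[i], end(regions)[i]) /
      (track$total / 1e6)
  }
  n <- length(regions)
  l2 <- function(case, ctrl) {
    vapply(seq_len(n), function(i)
      log2((norm_sum(case, i) + pseudocount) /
             (norm_sum(ctrl, i) + pseudocount)), 0)
  }
  tf_lfc <- l2(tf_case, tf_ctrl)
  mk_lfc <- l2(mark_case, mark_ctrl)

  prom <- promoter_ranges(annotation, promoter_window[1], promoter_window[2])
  hits <- findOverlaps(regions, prom, ignore.strand = TRUE)
  ri <- queryHits(hits)
  tab <- data.frame(region = ri,
                    gene_id = mcols(prom)$gene_id[subjectHits(hits)],
                    tf_log2fc = tf_lfc[ri], mark_log2fc = mk_lfc[ri],
                    stringsAsFactors = FALSE)
  tab$de_p <- de$pvalue[match(tab$gene_id, de$gene_id)]
  tab$pass <- !is.na(tab$de_p) & tab$tf_log2fc > fc_cut &
    tab$mark_log2fc > fc_cut & tab$de_p < p_cut
  list(table = tab, filtered = tab[tab$pass, , drop = FALSE])
}

#' Hypergeometric gene-set overlap test
#'
#' Upper-tail probability of drawing at least the observed overlap:
#' `P(X >= k)` with `X ~ hypergeometric(N = |universe|, K = |setA|,
#' n = |setB|)` and `k = |setA intersect setB|`.
#'
#' @param setA,setB Character vectors, both subsets of `universe`.
#' @param universe Character vector of all candidate genes.
#' @return A list with `overlap` (k) and `pvalue`.
#' @export
hypergeometric_overlap <- function(setA, setB, universe) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  out <- c(setdiff(setA, universe), setdiff(setB, universe))
  if (length(out))
    .stopf("gene(s) outside the universe: %s",
           paste(head(out, 5), collapse = ", "))
  k <- length(intersect(setA, setB))
  N <- length(universe); K <- length(setA); n <- length(setB)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(overlap = k, pvalue = p, N = N, K = K, n = n)
}

#' Reads-per-million normalisation
#'
#' `rpm(g) = counts(g) * 1e6 / total_mapped`.
#'
#' @param counts Non-negative numeric vector (or single-column matrix) of
#'   per-gene read counts.
#' @param total_mapped Total mapped reads (> 0); defaults to `sum(counts)`.
#' @return A numeric vector of RPM values, names preserved.
#' @export
rpm <- function(counts, total_mapped = sum(counts)) {
  counts <- drop(as.matrix(counts))
  if (any(counts < 0)) .stopf("counts must be non-negative")
  if (total_mapped <= 0) .stopf("total_mapped must be > 0")
  counts * 1e6 / total_mapped
}
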