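# Peak-set statistics: base composition, TSS geography, genomic-region
# classification and interval-set Jaccard similarity.

#' A/T composition test of a peak set against the genome
#'
#' Compares the A+T base fraction over the merged peak bases with the
#' genome-wide fraction (the background includes the peak bases, matching the
#' "whole genome" framing; set `exclude_peaks_from_background = TRUE` for a
#' peak-excluded background). Significance is the 2x2 Pearson chi-squared
#' test without continuity correction; N bases are excluded from both
#' numerator and denominator.
#'
#' @param peaks A non-empty `GRanges` within genome bounds.
#' @param genome A `DNAStringSet`.
#' @param exclude_peaks_from_background Logical; default `FALSE`.
#' @return An object of class `at_composition` with base counts, fractions,
#'   `chi2` and `pvalue`.
#' @export
at_composition_test <- function(peaks, genome,
                                exclude_peaks_from_background = FALSE) {
  if (!length(peaks)) .stopf("empty peak set")
  merged <- reduce(peaks, ignore.strand = TRUE)
  seqs <- interval_seqs(genome, merged)
  pk <- colSums(letterFrequency(seqs, c("A", "T", "G", "C")))
  peak_at <- pk[["A"]] + pk[["T"]]
  peak_gc <- pk[["G"]] + pk[["C"]]
  gf <- colSums(letterFrequency(genome, c("A", "T", "G", "C")))
  bg_at <- gf[["A"]] + gf[["T"]]
  bg_gc <- gf[["G"]] + gf[["C"]]
  if (exclude_peaks_from_background) {
    bg_at <- bg_at - peak_at
    bg_gc <- bg_gc - peak_gc
  }
  if (bg_at + bg_gc == 0) .stopf("genome has no non-N bases")
  if (peak_at + peak_gc == 0) .stopf("peak set covers no non-N bases")
  tab <- matrix(c(peak_at, peak_gc, bg_at, bg_gc), nrow = 2, byrow = TRUE)
  if (peak_at / (peak_at + peak_gc) == bg_at / (bg_at + bg_gc)) {
    chi2 <- 0; p <- 1  # identical proportions: exact null
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    chi2 <- unname(ct$statistic); p <- ct$p.value
  }
  structure(list(peak_at = unname(peak_at), peak_gc = unname(peak_gc),
                 bg_at = unname(bg_at), bg_gc = unname(bg_gc),
                 peak_at_fraction = unname(peak_at / (peak_at + peak_gc)),
                 bg_at_fraction = unname(bg_at / (bg_at + bg_gc)),
                 chi2 = chi2, pvalue = p,
                 background = if (exclude_peaks_from_background)
                   "peak-excluded" else "whole-genome"),
            class = "at_composition")
}

#' @export
print.at_composition <- function(x, ...) {
  cat(sprintf("A/T composition: peaks %.1f%% vs %s background %.1f%%\n",
              100 * x$peak_at_fraction, x$background, 100 * x$bg_at_fraction))
  cat(sprintf("  chi-squared = %.4g (df = 1), p = %.3g\n", x$chi2, x$pvalue))
  invisible(x)
}

# ---- TSS geography --------------------------------------------------------

# Signed distance from each peak midpoint to the nearest TSS, oriented by the
# gene's strand (negative = upstream of that gene).
.tss_distances <- function(peaks, annotation) {
  mid <- floor((start(peaks) + end(peaks)) / 2)
  chs <- as.character(seqnames(peaks))
  dist <- rep(NA_real_, length(peaks))
  for (ch in unique(chs)) {
    ann <- annotation[annotation$chrom == ch, , drop = FALSE]
    idx <- which(chs == ch)
    if (!nrow(ann)) next
    o <- order(ann$tss, ann$gene_id)
    tss <- ann$tss[o]; sgn <- ifelse(ann$strand[o] == "+", 1, -1)
    pos <- findInterval(mid[idx], tss)
    for (j in seq_along(idx)) {
      cand <- unique(pmin(pmax(c(pos[j], pos[j] + 1L), 1L), length(tss)))
      d <- mid[idx[j]] - tss[cand]
      best <- cand[which.min(abs(d))]
      dist[idx[j]] <- (mid[idx[j]] - tss[best]) * sgn[best]
    }
  }
  dist
}

#' Peak-to-TSS distance profile
#'
#' For each peak, the signed distance from its midpoint to the nearest TSS
#' (negative upstream, in the gene's strand orientation) is histogrammed over
#' `[-window_bp, +window_bp]`; densities are bin counts divided by the total
#' peak count. `fraction_within_50kb` is computed from the raw distances, not
#' the bins.
#'
#' @param peaks A `GRanges`.
#' @param annotation A non-empty [gene_annotation()].
#' @param window_bp Half-window of the histogram (default 100 kb).
#' @param bin_bp Bin width (default 2 kb); must not exceed `window_bp`.
#' @return An object of class `tss_distance_profile` with `breaks`, `mids`,
#'   `counts`, `density`, `distances` and `fraction_within_50kb`.
#' @export
tss_distance_profile <- function(peaks, annotation, window_bp = 1e5,
                                 bin_bp = 2000) {
  if (!nrow(annotation)) .stopf("empty annotation")
  if (window_bp < bin_bp) .stopf("window_bp must be >= bin_bp")
  d <- .tss_distances(peaks, annotation)
  if (anyNA(d)) .stopf("some peaks lie on chromosomes without any annotated gene")
  breaks <- seq(-window_bp, window_bp, by = bin_bp)
  if (breaks[length(breaks)] < window_bp) breaks <- c(breaks, window_bp)
  inwin <- d >= -window_bp & d <= window_bp
  counts <- as.integer(table(cut(d[inwin], breaks, include.lowest = TRUE,
                                 right = FALSE)))
  structure(list(breaks = breaks, mids = (head(breaks, -1) + breaks[-1]) / 2,
                 counts = counts, density = counts / length(d),
                 distances = d,
                 fraction_within_50kb = mean(abs(d) <= 50000),
                 n_peaks = length(d)),
            class = "tss_distance_profile")
}

#' @export
print.tss_distance_profile <- function(x, ...) {
  cat(sprintf("TSS distance profile: %d peaks, %.1f%% within +/-50 kb of a TSS\n",
              x$n_peaks, 100 * x$fraction_within_50kb))
  invisible(x)
}

#' Classify peaks into genomic-region categories
#'
#' Each peak is assigned exactly one category by the position of its midpoint
#' with fixed precedence promoter > enhancer > exon > intron > intergenic.
#' `intron` means inside a gene body but not in the exon set; when no exon or
#' enhancer set is supplied those categories collapse downward.
#'
#' @param peaks A `GRanges`.
#' @param annotation A [gene_annotation()].
#' @param exons,enhancers Optional `GRanges` annotation sets.
#' @param promoter_window `c(upstream, downstream)` around the TSS,
#'   strand-aware (default 2000/500).
#' @return A named integer vector over the five categories (summing to the
#'   peak count) with the per-peak assignment in attribute `"assignment"`.
#' @export
classify_regions <- function(peaks, annotation, exons = NULL,
                             enhancers = NULL, promoter_window = c(2000, 500)) {
  mid <- GRanges(seqnames(peaks),
                 IRanges(floor((start(peaks) + end(peaks)) / 2), width = 1))
  prom <- promoter_ranges(annotation, promoter_window[1], promoter_window[2])
  bodies <- GRanges(annotation$chrom, IRanges(annotation$start, annotation$end))
  in_set <- function(set) {
    if (is.null(set) || !length(set)) rep(FALSE, length(mid))
    else overlapsAny(mid, set, ignore.strand = TRUE)
  }
  cls <- rep("intergenic", length(mid))
  cls[in_set(bodies)] <- "intron"
  cls[in_set(exons)] <- "exon"
  cls[in_set(enhancers)] <- "enhancer"
  cls[in_set(prom)] <- "promoter"
  lev <- c("promoter", "enhancer", "exon", "intron", "intergenic")
  out <- table(factor(cls, levels = lev))
  res <- setNames(as.integer(out), lev)
  attr(res, "assignment") <- cls
  res
}

# ---- Jaccard --------------------------------------------------------------

# Light-weight merged-interval arithmetic on numeric vectors (1-based closed),
# used for the permutation loop where GRanges construction would dominate.
.merge_iv <- function(s, e) {
  o <- order(s)
  s <- s[o]; e <- e[o]
  n <- length(s)
  if (n <= 1) return(list(s = s, e = e))
  ce <- cummax(e)
  brk <- c(TRUE, s[-1] > ce[-n] + 1)
  grp <- cumsum(brk)
  list(s = s[brk], e = as.numeric(tapply(e, grp, max)))
}

# Total overlap (bp) between two merged, sorted interval lists: sweep over the
# elementary segments defined by all boundaries.
.inter_bp <- function(as, ae, bs, be) {
  if (!length(as) || !length(bs)) return(0)
  pts <- sort(unique(c(as, ae + 1, bs, be + 1)))
  seg_s <- pts[-length(pts)]
  seg_len <- diff(pts)
  ia <- findInterval(seg_s, as)
  in_a <- ia >= 1 & seg_s <= ae[pmax(ia, 1)]
  ib <- findInterval(seg_s, bs)
  in_b <- ib >= 1 & seg_s <= be[pmax(ib, 1)]
  sum(seg_len[in_a & in_b])
}

#' Genomic Jaccard statistic with a permutation p-value
#'
#' `jaccard_index` computes intersection bp / union bp on internally merged
#' interval sets, exactly as `bedtools jaccard` defines the statistic.
#' `jaccard_with_permutation` adds a permutation p-value obtained by
#' repeatedly re-placing the intervals of `A` uniformly within their own
#' chromosomes (lengths preserved) and using the add-one estimator
#' `(1 + #\{J* >= J\}) / (1 + n_permutations)`.
#'
#' @param A,B Non-empty `GRanges`.
#' @return `jaccard_index`: a list with `intersection_bp`, `union_bp`,
#'   `jaccard`.
#' @export
jaccard_index <- function(A, B) {
  if (!length(A) || !length(B)) .stopf("Jaccard requires two non-empty sets")
  A <- reduce(granges(A), ignore.strand = TRUE)
  B <- reduce(granges(B), ignore.strand = TRUE)
  lev <- union(seqlevels(A), seqlevels(B))
  seqlevels(A) <- lev
  seqlevels(B) <- lev
  inter <- sum(width(GenomicRanges::intersect(A, B, ignore.strand = TRUE)))
  uni <- sum(width(A)) + sum(width(B)) - inter
  list(intersection_bp = inter, union_bp = uni, jaccard = inter / uni)
}

#' @rdname jaccard_index
#' @param genome Genome or named chromosome lengths (needed to place
#'   permuted intervals).
#' @param n_permutations Number of permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @return `jaccard_with_permutation`: an object of class `jaccard_result`
#'   adding `permutation_p`, `n_permutations` and `seed`.
#' @export
jaccard_with_permutation <- function(A, B, genome, n_permutations = 1000,
                                     seed = 1) {
  obs <- jaccard_index(A, B)
  lens <- .genome_lengths(genome)
  A <- reduce(granges(A), ignore.strand = TRUE)
  B <- reduce(granges(B), ignore.strand = TRUE)
  chs <- as.character(seqnames(A))
  w <- width(A)
  maxstart <- unname(lens[chs]) - w + 1L
  if (any(maxstart < 1)) .stopf("an interval of A is longer than its chromosome")
  bch <- as.character(seqnames(B))
  b_by_ch <- lapply(unique(chs), function(ch) {
    i <- bch == ch
    list(s = start(B)[i], e = end(B)[i])
  })
  names(b_by_ch) <- unique(chs)
  len_b <- sum(width(B))
  set.seed(.substream(seed, "jaccard"))
  ge <- 0L
  for (i in seq_len(n_permutations)) {
    newstart <- floor(runif(length(A), 1, maxstart + 1))
    inter <- 0; len_a <- 0
    for (ch in names(b_by_ch)) {
      sel <- chs == ch
      m <- .merge_iv(newstart[sel], newstart[sel] + w[sel] - 1)
      len_a <- len_a + sum(m$e - m$s + 1)
      inter <- inter + .inter_bp(m$s, m$e, b_by_ch[[ch]]$s, b_by_ch[[ch]]$e)
    }
    jstar <- inter / (len_a + len_b - inter)
    if (jstar >= obs$jaccard) ge <- ge + 1L
  }
  structure(c(obs, list(permutation_p = (1 + ge) / (1 + n_permutations),
                        n_permutations = n_permutations, seed = seed)),
            class = "jaccard_result")
}

#' @export
print.jaccard_result <- function(x, ...) {
  cat(sprintf("Jaccard = %.4g (intersection %d bp / union %d bp), permutation p = %.4g (%d permutations)\n",
              x$jaccard, x$intersection_bp, x$union_bp, x$permutation_p,
              x$n_permutations))
  invisible(x)
}
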