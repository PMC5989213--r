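# Synthetic-data generators.
#
# Emulates the statistical structure the downstream stages assume: an
# AT-biased genome, a peak set with elevated A/T content and one planted
# consensus-motif instance per peak (a subset of peaks centred on TSSs),
# two-condition Poisson coverage with promoter-localised enrichment, and
# negative-binomial expression counts whose true log2 fold changes are
# linearly coupled to the promoter accessibility ratio. Every generator is
# bit-for-bit reproducible given (parameters, seed); substream seeds are
# derived per generator so adding one never perturbs another.

.sample_bases <- function(n, at_fraction) {
  p <- c(at_fraction / 2, at_fraction / 2, (1 - at_fraction) / 2,
         (1 - at_fraction) / 2)
  # A, T, C, G as UTF-8 code points; intToUtf8 assembles the string directly
  intToUtf8(c(65L, 84L, 67L, 71L)[sample.int(4L, n, replace = TRUE, prob = p)])
}

#' Simulate an AT-biased genome with non-overlapping genes
#'
#' Bases are i.i.d. with `P(A) = P(T) = base_at_fraction / 2`; genes are
#' placed uniformly without overlap, strands are fair coin flips.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param base_at_fraction Genome-wide A+T fraction in (0, 1); default 0.59,
#'   the human genome figure the background emulates.
#' @param n_genes Total number of genes.
#' @param gene_length Gene span (bp).
#' @param seed Integer seed.
#' @return A list with `genome` (`DNAStringSet`), `annotation`
#'   ([gene_annotation()]) and `base_at_fraction`.
#' @export
simulate_genome <- function(n_chrom = 2, chrom_length = 5e6,
                            base_at_fraction = 0.59, n_genes = 500,
                            gene_length = 1000, seed = 1) {
  if (base_at_fraction <= 0 || base_at_fraction >= 1)
    .stopf("base_at_fraction must lie in (0, 1)")
  if (n_genes * gene_length > n_chrom * chrom_length)
    .stopf("cannot place %d genes of %d bp on %d x %d bp chromosomes",
           n_genes, gene_length, n_chrom, chrom_length)
  set.seed(.substream(seed, "genome"))
  chrom_names <- sprintf("chr%d", seq_len(n_chrom))
  seqs <- vapply(chrom_names, function(ch)
    .sample_bases(chrom_length, base_at_fraction), "")
  genome <- DNAStringSet(seqs)

  # spread genes across chromosomes, then place without overlap per chromosome
  per <- rep(n_genes %/% n_chrom, n_chrom)
  extra <- n_genes %% n_chrom
  if (extra) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  recs <- list()
  gid <- 0L
  for (i in seq_len(n_chrom)) {
    k <- per[i]
    if (!k) next
    if (k * gene_length > chrom_length)
      .stopf("cannot place %d genes of %d bp on a %d bp chromosome",
             k, gene_length, chrom_length)
    # uniform non-overlapping placement: draw sorted anchors, then offset
    anchors <- sort(sample.int(chrom_length - k * gene_length + 1L, k))
    starts <- anchors + (seq_len(k) - 1L) * gene_length
    strands <- c("+", "-")[sample.int(2L, k, replace = TRUE)]
    recs[[i]] <- data.frame(gene_id = sprintf("g%04d", gid + seq_len(k)),
                            chrom = chrom_names[i], strand = strands,
                            start = starts, end = starts + gene_length - 1L,
                            stringsAsFactors = FALSE)
    gid <- gid + k
  }
  recs <- do.call(rbind, recs)
  annotation <- gene_annotation(recs$gene_id, recs$chrom, recs$strand,
                                recs$start, recs$end, genome)
  list(genome = genome, annotation = annotation,
       base_at_fraction = base_at_fraction)
}

# Realise one concrete instance of an IUPAC consensus (degenerate positions
# sampled uniformly among their allowed bases).
.instantiate_motif <- function(motif) {
  codes <- IUPAC_CODE_MAP
  chars <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(chars, names(codes))
  if (length(bad)) .stopf("invalid IUPAC code(s) in motif: %s",
                          paste(bad, collapse = ", "))
  paste(vapply(chars, function(ch) {
    opts <- strsplit(codes[[ch]], "")[[1]]
    opts[sample.int(length(opts), 1L)]
  }, ""), collapse = "")
}

#' Simulate a peak set with planted composition and motif
#'
#' `promoter_fraction` of the peaks are centred on randomly chosen TSSs (the
#' corresponding genes become the ground-truth bound set); the remainder are
#' uniform. Peak sequences are rewritten in place to i.i.d. bases at
#' `peak_at_fraction` A/T, then one concrete instance of `motif` is planted
#' per peak at a random offset.
#'
#' @param genome,annotation Output of [simulate_genome()].
#' @param n_peaks Number of peaks.
#' @param peak_length Peak width (bp); must be at least the motif length.
#' @param promoter_fraction Fraction of peaks centred on TSSs, in `[0, 1]`.
#' @param peak_at_fraction A+T fraction inside peaks (default 0.66, the
#'   elevated composition the peak-set statistics are designed to detect
#'   against a 0.59 background).
#' @param motif IUPAC consensus planted once per peak (default `"AAAATAW"`).
#' @param seed Integer seed.
#' @return A list with `peaks` (`GRanges`), the modified `genome`, and a
#'   `truth` record (`bound_genes`, `planted_motif`, `peak_at_fraction`,
#'   `background_at_fraction`, `seed`).
#' @export
simulate_peaks <- function(genome, annotation, n_peaks = 300,
                           peak_length = 500, promoter_fraction = 1 / 3,
                           peak_at_fraction = 0.66, motif = "AAAATAW",
                           seed = 1) {
  if (promoter_fraction < 0 || promoter_fraction > 1)
    .stopf("promoter_fraction must lie in [0, 1]")
  if (peak_length < nchar(motif))
    .stopf("peak_length (%d) is shorter than the motif (%d bp)",
           peak_length, nchar(motif))
  set.seed(.substream(seed, "peaks"))
  lens <- .genome_lengths(genome)
  half <- peak_length %/% 2L

  n_prom <- round(promoter_fraction * n_peaks)
  replace <- n_prom > nrow(annotation)
  sel <- if (n_prom)
    sample(seq_len(nrow(annotation)), n_prom, replace = replace) else integer(0)
  bound <- annotation[sel, , drop = FALSE]
  prom_start <- pmin(pmax(bound$tss - half, 1L),
                     unname(lens[bound$chrom]) - peak_length + 1L)

  n_unif <- n_peaks - n_prom
  uchr <- sample(names(lens), n_unif, replace = TRUE,
                 prob = lens / sum(lens))
  ustart <- vapply(uchr, function(ch)
    sample.int(unname(lens[[ch]]) - peak_length + 1L, 1L), 0L)

  chrom <- c(bound$chrom, uchr)
  starts <- as.integer(c(prom_start, ustart))
  peaks <- .as_sorted_granges(chrom, starts, starts + peak_length - 1L,
                              genome = genome)

  # rewrite pass: peak-interior composition (merged so overlaps are written once)
  merged <- reduce(peaks, ignore.strand = TRUE)
  mch <- as.character(seqnames(merged))
  for (ch in unique(mch)) {
    idx <- which(mch == ch)
    at <- IRanges(start(merged)[idx], end(merged)[idx])
    val <- DNAStringSet(vapply(width(at), function(w)
      .sample_bases(w, peak_at_fraction), ""))
    genome[[ch]] <- replaceAt(genome[[ch]], at, val)
  }
  # planting pass: one motif instance per peak at a random offset; on the
  # rare occasion two plants collide (overlapping peaks) the first wins
  mlen <- nchar(motif)
  inst <- vapply(seq_along(peaks), function(i) .instantiate_motif(motif), "")
  off <- sample.int(peak_length - mlen + 1L, length(peaks), replace = TRUE)
  plant_at <- start(peaks) + off - 1L
  pch <- as.character(seqnames(peaks))
  for (ch in unique(pch)) {
    idx <- which(pch == ch)
    idx <- idx[order(plant_at[idx])]
    last_end <- -1L
    keep <- logical(length(idx))
    for (j in seq_along(idx)) {
      s <- plant_at[idx[j]]
      if (s > last_end) { keep[j] <- TRUE; last_end <- s + mlen - 1L }
    }
    idx <- idx[keep]
    genome[[ch]] <- replaceAt(genome[[ch]],
                              IRanges(plant_at[idx], width = mlen),
                              DNAStringSet(inst[idx]))
  }

  bg_at <- sum(letterFrequency(genome, "AT")) / sum(width(genome))
  truth <- list(bound_genes = sort(unique(bound$gene_id)),
                planted_motif = toupper(motif),
                peak_at_fraction = peak_at_fraction,
                background_at_fraction = bg_at,
                seed = seed)
  list(peaks = peaks, genome = genome, truth = truth)
}

#' Simulate two-condition coverage with promoter-localised enrichment
#'
#' Background signal is per-base Poisson(`depth`). Over each bound gene's
#' promoter window (TSS +/- `promoter_halfwidth`), the rate is
#' `depth * enrichment` in the control ("empty") condition and
#' `depth * enrichment * condition_scale` in the "case" condition, so the
#' per-gene accessibility effect of the case condition is `condition_scale`
#' at bound genes and 1 elsewhere.
#'
#' @param genome Genome or named chromosome lengths.
#' @param annotation A [gene_annotation()].
#' @param truth Truth record from [simulate_peaks()] (its `bound_genes` are
#'   the enriched set); updated in the return value.
#' @param depth Background per-base Poisson mean (> 0).
#' @param enrichment Promoter enrichment factor (>= 1).
#' @param condition_scale Case/control promoter signal ratio (>= 1).
#' @param promoter_halfwidth Half-width of the planted window (bp).
#' @param seed Integer seed.
#' @return A list with `empty` and `case` [coverage_track()]s and the updated
#'   `truth` (gains `accessibility_effect`, a named per-gene vector).
#' @export
simulate_coverage <- function(genome, annotation, truth, depth = 10,
                              enrichment = 5, condition_scale = 4,
                              promoter_halfwidth = 1000, seed = 1) {
  if (depth <= 0) .stopf("depth must be > 0")
  if (enrichment < 1 || condition_scale < 1)
    .stopf("enrichment and condition_scale must be >= 1")
  lens <- .genome_lengths(genome)
  bound <- annotation[annotation$gene_id %in% truth$bound_genes, , drop = FALSE]

  make_rates <- function(prom_rate) {
    rates <- lapply(lens, function(L) rep(depth, L))
    for (j in seq_len(nrow(bound))) {
      ch <- bound$chrom[j]
      lo <- max(1L, bound$tss[j] - promoter_halfwidth)
      hi <- min(unname(lens[[ch]]), bound$tss[j] + promoter_halfwidth)
      rates[[ch]][lo:hi] <- prom_rate
    }
    rates
  }
  draw <- function(rates, label) {
    set.seed(.substream(seed, label))
    coverage_track(lapply(rates, function(r) Rle(rpois(length(r), r))))
  }
  empty <- draw(make_rates(depth * enrichment), "coverage-empty")
  case <- draw(make_rates(depth * enrichment * condition_scale), "coverage-case")

  eff <- setNames(rep(1, nrow(annotation)), annotation$gene_id)
  eff[truth$bound_genes] <- condition_scale
  truth$accessibility_effect <- eff
  list(empty = empty, case = case, truth = truth)
}

#' Simulate two-condition expression counts coupled to accessibility
#'
#' True log2 fold changes are `coupling * log2(accessibility_effect)` plus
#' `Normal(0, sigma_noise)` (the effect is 1 at unbound genes, so their true
#' fold change is pure noise). Counts are negative binomial with variance
#' `mu + dispersion * mu^2`; the case-condition mean is scaled by
#' `2^true_log2fc`. The returned DE table carries moment estimates with
#' Wald-style normal-approximation p-values (deliberately simple plumbing,
#' not a DESeq2-style model fit) alongside the true fold changes.
#'
#' @param annotation A [gene_annotation()].
#' @param truth Truth record carrying `accessibility_effect`.
#' @param coupling Slope linking log2 accessibility ratio to expression
#'   log2FC.
#' @param base_mean Control-condition mean count.
#' @param dispersion Negative-binomial dispersion `alpha` (> 0).
#' @param sigma_noise SD of the biological noise on true log2FC.
#' @param n_replicates Replicates per condition (>= 2).
#' @param seed Integer seed.
#' @return A list with `counts` (list of two gene x replicate matrices),
#'   `de` (a [de_table()] with an extra `true_log2fc` column) and the updated
#'   `truth` (gains `true_log2fc` and `coupling`).
#' @export
simulate_expression <- function(annotation, truth, coupling = 1,
                                base_mean = 200, dispersion = 0.1,
                                sigma_noise = 0.25, n_replicates = 3,
                                seed = 1) {
  if (n_replicates < 2) .stopf("n_replicates must be >= 2")
  if (dispersion <= 0) .stopf("dispersion must be > 0")
  set.seed(.substream(seed, "expression"))
  genes <- annotation$gene_id
  n <- length(genes)
  eff <- truth$accessibility_effect
  if (is.null(eff)) eff <- setNames(rep(1, n), genes)
  true_lfc <- coupling * log2(unname(eff[genes])) +
    if (sigma_noise > 0) rnorm(n, 0, sigma_noise) else 0

  size <- 1 / dispersion
  mu_case <- base_mean * 2^true_lfc
  counts_empty <- matrix(rnbinom(n * n_replicates, mu = base_mean, size = size),
                         nrow = n,
                         dimnames = list(genes, sprintf("empty_%d", seq_len(n_replicates))))
  counts_case <- matrix(rnbinom(n * n_replicates, mu = rep(mu_case, n_replicates),
                                size = size),
                        nrow = n,
                        dimnames = list(genes, sprintf("case_%d", seq_len(n_replicates))))

  mu1 <- rowMeans(counts_empty); mu2 <- rowMeans(counts_case)
  lfc_hat <- log2((mu2 + 0.5) / (mu1 + 0.5))
  v1 <- (mu1 + dispersion * mu1^2) / n_replicates
  v2 <- (mu2 + dispersion * mu2^2) / n_replicates
  se2 <- (v1 / (mu1 + 0.5)^2 + v2 / (mu2 + 0.5)^2) / log(2)^2
  z <- lfc_hat / sqrt(se2)
  p <- 2 * pnorm(-abs(z))
  de <- de_table(genes, lfc_hat, p, p.adjust(p, "BH"), (mu1 + mu2) / 2)
  de$true_log2fc <- true_lfc

  truth$true_log2fc <- setNames(true_lfc, genes)
  truth$coupling <- coupling
  list(counts = list(empty = counts_empty, case = counts_case),
       de = de, truth = truth)
}
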