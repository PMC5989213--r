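# End-to-end orchestration: synthetic-data generation followed by every
# analysis stage, with a serialisable, bit-reproducible report.

#' Pipeline configuration
#'
#' Collects every generator and stage parameter with its standard default
#' (profiling window 2000/10000 bp, 200 bp bins, ratio window 1500/5000 bp,
#' 50 threshold cycles from 0 by 0.1, 1000 bp correlation bins, DEG FDR
#' 0.001, coverage log2FC cut 0.5, expression p cut 0.05) plus one global
#' seed from which every stage derives its own substream.
#'
#' @param seed Global integer seed.
#' @param n_chrom,chrom_length,base_at_fraction,n_genes,gene_length Genome
#'   generator parameters (see [simulate_genome()]).
#' @param n_peaks,peak_length,promoter_fraction,peak_at_fraction,motif Peak
#'   generator parameters (see [simulate_peaks()]).
#' @param depth,enrichment,condition_scale,promoter_halfwidth Coverage
#'   generator parameters (see [simulate_coverage()]).
#' @param coupling,base_mean,dispersion,sigma_noise,n_replicates Expression
#'   generator parameters (see [simulate_expression()]).
#' @param profile_before,profile_after,bin_size TSS profiling parameters.
#' @param ratio_before,ratio_after,cycles,threshold_start,threshold_step
#'   Accessibility-expression correlation parameters.
#' @param marks_bin Track-correlation bin width (bp).
#' @param jaccard_permutations Permutations for the Jaccard p-value.
#' @param kmer_k,kmer_shuffles Motif-enrichment parameters.
#' @param promoter_up,promoter_down Promoter window for binding assignment.
#' @param fdr_cut,fc_cut,p_cut Integration thresholds.
#' @param out_dir Optional directory; when set, [run_pipeline()] writes the
#'   JSON report and TSV tables there.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            n_chrom = 2, chrom_length = 5e6,
                            base_at_fraction = 0.59, n_genes = 500,
                            gene_length = 1000,
                            n_peaks = 300, peak_length = 500,
                            promoter_fraction = 1 / 3,
                            peak_at_fraction = 0.66, motif = "AAAATAW",
                            depth = 10, enrichment = 5, condition_scale = 4,
                            promoter_halfwidth = 1000,
                            coupling = 1, base_mean = 200, dispersion = 0.1,
                            sigma_noise = 0.25, n_replicates = 3,
                            profile_before = 2000, profile_after = 10000,
                            bin_size = 200,
                            ratio_before = 1500, ratio_after = 5000,
                            cycles = 50, threshold_start = 0,
                            threshold_step = 0.1,
                            marks_bin = 1000, jaccard_permutations = 1000,
                            kmer_k = 7, kmer_shuffles = 10,
                            promoter_up = 2500, promoter_down = 2500,
                            fdr_cut = 0.001, fc_cut = 0.5, p_cut = 0.05,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  num <- cfg[!vapply(cfg, is.character, TRUE) & !vapply(cfg, is.null, TRUE)]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x), TRUE)))
    .stopf("all numeric configuration values must be finite scalars")
  if (cfg$n_genes * cfg$gene_length > cfg$n_chrom * cfg$chrom_length)
    .stopf("configuration error: genes do not fit on the genome")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Simulate a complete ground-truthed dataset
#'
#' Runs the four generators in sequence (genome/annotation, peaks, coverage,
#' expression) under substreams of one seed.
#'
#' @param config A [pipeline_config()].
#' @return A list with `genome`, `annotation`, `peaks`, `tracks`
#'   (`$empty`, `$case`), `counts`, `de` and the accumulated `truth` record.
#' @export
simulate_dataset <- function(config = pipeline_config()) {
  c_ <- config
  gen <- simulate_genome(c_$n_chrom, c_$chrom_length, c_$base_at_fraction,
                         c_$n_genes, c_$gene_length, seed = c_$seed)
  pk <- simulate_peaks(gen$genome, gen$annotation, c_$n_peaks, c_$peak_length,
                       c_$promoter_fraction, c_$peak_at_fraction, c_$motif,
                       seed = c_$seed)
  cv <- simulate_coverage(pk$genome, gen$annotation, pk$truth, c_$depth,
                          c_$enrichment, c_$condition_scale,
                          c_$promoter_halfwidth, seed = c_$seed)
  ex <- simulate_expression(gen$annotation, cv$truth, c_$coupling,
                            c_$base_mean, c_$dispersion, c_$sigma_noise,
                            c_$n_replicates, seed = c_$seed)
  list(genome = pk$genome, annotation = gen$annotation, peaks = pk$peaks,
       tracks = list(empty = cv$empty, case = cv$case),
       counts = ex$counts, de = ex$de, truth = ex$truth)
}

#' Run the full synthetic pipeline
#'
#' Generates a dataset from the configuration, then runs every analysis
#' stage: A/T composition, k-mer motif enrichment, TSS-distance profile,
#' genomic-region classification, Jaccard against a second independently
#' generated peak set, TSS coverage profiling with binning and aggregation,
#' the iterative-threshold accessibility-expression correlation, genome-wide
#' binned track correlation, and the promoter-binding x DEG integration with
#' hypergeometric overlap and RPM. Two runs with an identical configuration
#' produce bit-identical reports.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return A list of class `pipeline_report`: `config`, `summary` (flat named
#'   numbers per stage) and `stages` (full stage objects). When
#'   `config$out_dir` is set, `report.json` plus TSV tables are written there.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  c_ <- config
  say("simulating dataset (seed %d)", c_$seed)
  ds <- simulate_dataset(c_)

  say("peak statistics")
  atc <- at_composition_test(ds$peaks, ds$genome)
  km <- kmer_motif_enrichment(ds$peaks, ds$genome, k = c_$kmer_k,
                              n_shuffles = c_$kmer_shuffles, seed = c_$seed)
  top_hits <- scan_consensus(ds$genome, ds$truth$planted_motif, ds$peaks)
  tssd <- tss_distance_profile(ds$peaks, ds$annotation)
  cls <- classify_regions(ds$peaks, ds$annotation)
  # second condition's peak set: same generator, independent substream
  pk2 <- simulate_peaks(ds$genome, ds$annotation, c_$n_peaks, c_$peak_length,
                        c_$promoter_fraction, c_$peak_at_fraction, c_$motif,
                        seed = .substream(c_$seed, "peaks-wt"))
  jac <- jaccard_with_permutation(ds$peaks, pk2$peaks, ds$genome,
                                  n_permutations = c_$jaccard_permutations,
                                  seed = c_$seed)

  say("TSS profiling")
  pm <- tss_profile(ds$tracks$case, ds$annotation, c_$profile_before,
                    c_$profile_after)
  pb <- bin_profile(pm, c_$bin_size)
  agg <- aggregate_profile(pb)

  say("correlation tools")
  ratios <- region_condition_ratio(ds$tracks$case, ds$tracks$empty,
                                   ds$annotation, c_$ratio_before,
                                   c_$ratio_after)
  thr <- iterative_threshold_correlation(ratios, ds$de, c_$cycles,
                                         c_$threshold_start, c_$threshold_step)
  marks <- binned_track_correlation(ds$tracks$empty, ds$tracks$case,
                                    c_$marks_bin)

  say("integration")
  bound <- assign_peaks_to_promoters(ds$peaks, ds$annotation, c_$promoter_up,
                                     c_$promoter_down)
  inter <- intersect_bound_degs(bound, ds$de, c_$fdr_cut)
  hyp <- hypergeometric_overlap(bound, inter$deg_genes, ds$annotation$gene_id)
  rpm_empty <- rpm(ds$counts$empty[, 1])

  top_kmer <- km$kmer[1]
  matches_planted <- isTRUE(matches_consensus(top_kmer,
                                              ds$truth$planted_motif))

  summary <- list(
    n_peaks = length(ds$peaks),
    peak_at_fraction = atc$peak_at_fraction,
    background_at_fraction = atc$bg_at_fraction,
    at_chi2 = atc$chi2,
    at_pvalue = atc$pvalue,
    top_kmer = top_kmer,
    top_kmer_z = km$z[1],
    top_kmer_matches_planted = as.integer(matches_planted),
    n_consensus_matches_in_peaks = length(top_hits),
    fraction_within_50kb = tssd$fraction_within_50kb,
    region_counts = as.list(setNames(as.integer(cls), names(cls))),
    jaccard = jac$jaccard,
    jaccard_p = jac$permutation_p,
    profile_genes_complete = sum(pb$complete),
    aggregate_peak_offset = as.numeric(names(agg)[which.max(agg)]),
    threshold_corr_first_r = thr$pearson_r[1],
    threshold_corr_first_n = thr$n_genes[1],
    marks_corr_r = marks$pearson_r,
    marks_corr_bins = marks$n_bins,
    n_bound_genes = length(bound),
    n_deg = length(inter$deg_genes),
    n_co_occurring = length(inter$co_occurring),
    fraction_up = inter$fraction_up,
    binomial_p = inter$binomial_p,
    hypergeometric_p = hyp$pvalue,
    rpm_total = sum(rpm_empty)
  )
  report <- list(config = unclass(c_), summary = summary,
                 stages = list(at_composition = atc, kmer = km,
                               tss_distance = tssd, regions = cls,
                               jaccard = jac, aggregate = agg,
                               threshold_correlation = thr, marks = marks,
                               intersection = inter, hypergeometric = hyp))
  class(report) <- "pipeline_report"
  if (!is.null(c_$out_dir)) .write_report(report, ds, c_$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("pipeline report (seed", x$config$seed, ")\n")
  cat(sprintf("  peaks: %d; A/T %.1f%% vs %.1f%% (chi2 p = %.3g)\n",
              s$n_peaks, 100 * s$peak_at_fraction,
              100 * s$background_at_fraction, s$at_pvalue))
  cat(sprintf("  top k-mer: %s (z = %.1f); %.1f%% of peaks within 50 kb of a TSS\n",
              s$top_kmer, s$top_kmer_z, 100 * s$fraction_within_50kb))
  cat(sprintf("  jaccard = %.3g (p = %.3g); threshold-corr r = %.3f; marks r = %.3f\n",
              s$jaccard, s$jaccard_p, s$threshold_corr_first_r, s$marks_corr_r))
  cat(sprintf("  %d bound x %d DEG -> %d co-occurring; %.1f%% up (p = %.3g)\n",
              s$n_bound_genes, s$n_deg, s$n_co_occurring,
              100 * s$fraction_up, s$binomial_p))
  invisible(x)
}

.write_report <- function(report, ds, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_json(list(config = report$config, summary = report$summary),
             file.path(out_dir, "report.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.table(as.data.frame(report$stages$kmer),
              file.path(out_dir, "kmer_enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(report$stages$threshold_correlation),
              file.path(out_dir, "threshold_correlation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_de_table(ds$de, file.path(out_dir, "de_table.tsv"))
  write_bed(ds$peaks, file.path(out_dir, "peaks.bed"))
  invisible(out_dir)
}
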