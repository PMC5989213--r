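---
title: "Methods: peak composition, TSS profiling and accessibility-expression integration"
author: "epihub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak composition, TSS profiling and accessibility-expression integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

epihub implements the computational core of a common regulatory-genomics
study design: a DNA-binding factor is profiled by ChIP-Seq (peak intervals
and coverage tracks), chromatin accessibility by ATAC-Seq, and transcription
by RNA-Seq in two conditions, and the question is whether the factor binds
AT-rich DNA through a short consensus, sits at promoters, opens chromatin
there, and activates the genes it binds. This vignette describes each
statistical procedure, its assumptions, the tunable parameters, and the
design decisions taken where more than one reasonable definition exists.

## Coordinate model and containers

Internally every interval is a `GRanges` (1-based, closed), the R field
convention. BED and bedGraph files (0-based, half-open) are converted at the
file boundary, so a BED line `chr1 0 100` becomes `chr1:1-100` with identical
content. GTF gene coordinates map 1:1. The TSS of a plus-strand gene is the
first base of its span; for a minus-strand gene it is the last base, which
keeps the two strands symmetric. Unknown chromosomes or out-of-bounds records
in any input are errors, never silent drops: dropped records would corrupt
the coverage totals used as normalisation constants downstream.

Coverage is held per chromosome as a run-length encoded vector of
non-negative per-base signal with a cached genome-wide total. bedGraph is the
normative text format; the writer emits run-length merged non-zero runs, so
write/read round trips reproduce per-base arrays exactly.

## Peak composition and the chi-squared test

`at_composition_test()` compares the A+T fraction over the merged peak bases
with the genome-wide fraction, using the 2x2 Pearson chi-squared test without
continuity correction (counts in any realistic input are 1e5-1e9, where the
correction is negligible). The background deliberately *includes* the peak
bases — the comparison is "peaks versus the entire genome" — with a
`exclude_peaks_from_background` flag for the peak-excluded sensitivity
analysis. N bases are excluded from both numerator and denominator.

## k-mer consensus enrichment

De novo motif discovery is implemented as canonical k-mer enrichment: each
k-mer is pooled with its reverse complement, counted over the peak
sequences, and compared with its mean and SD across dinucleotide-preserving
shuffles (Altschul-Erikson Eulerian-path shuffle) of the same sequences.
A mononucleotide background would be badly anticonservative in AT-rich
sequence, where poly-A/poly-T k-mers are inflated by dinucleotide stacking;
conditioning on the exact dinucleotide content removes that artefact. The
z-score denominator is the empirical shuffle SD floored at `sqrt(mean + 1)`,
a Poisson-scale floor that keeps rare k-mers from producing unstable scores
when a handful of shuffles happen to agree. Defaults: `k = 7` (the length of
an AT-hook-style consensus such as `AAAATAW`), 10 shuffles.

Two caveats are inherent to the method. First, one-base-shifted variants of
a planted consensus co-occur with it and can outrank it when the number of
peaks is small; at a few hundred peaks the exact consensus reliably tops the
table. Second, the z-scores are enrichment rankings, not calibrated
p-values: with ~8000 canonical 7-mers the null maximum |z| regularly
exceeds any fixed small threshold, so the package reports z for ranking and
leaves significance to the planted-truth recovery tests.

`scan_consensus()` reports all matches of an IUPAC consensus on both strands,
deduplicated and sorted, optionally restricted to regions.

## Peak geography

`tss_distance_profile()` measures the signed distance from each peak
*midpoint* to the nearest TSS (negative = upstream in the gene's
orientation) and histograms it; midpoints give each peak one vote, which is
the natural reading of a peak-level density plot. The within-50-kb fraction
is computed from raw distances, not bins. `classify_regions()` assigns each
peak midpoint to exactly one of promoter > enhancer > exon > intron >
intergenic, in that fixed precedence, so counts always sum to the peak
count; enhancer and exon sets are optional and collapse downward when
absent. The default classification promoter window is 2000 bp upstream /
500 bp downstream of the TSS, a common convention.

## Jaccard similarity with permutation p-value

`jaccard_index()` computes intersection bp / union bp on internally merged
sets, the bedtools definition. Because no analytic null exists for interval
sets with realistic length structure, `jaccard_with_permutation()` obtains a
p-value by re-placing the intervals of the first set uniformly within their
own chromosomes (lengths preserved, 1000 permutations by default) and using
the add-one estimator `(1 + #[J* >= J]) / (1 + n)`, which never returns 0.
The permutation loop uses a light-weight sweep-line intersection on plain
numeric vectors; a test asserts its exact agreement with the `GRanges`
computation.

## TSS-anchored profiling

`tss_profile()` builds the genes-by-positions matrix of per-base coverage in
TSS-anchored, strand-oriented coordinates (window defaults -2000..+10000 bp).
Each value is divided by the track total over 1e6 — signal per million
coverage units — so absolute sequencing depth cancels; "total coverage" is
interpreted as summed per-base depth, which differs from mapped-read count
only by the mean read length, a constant that cancels in every downstream
ratio. Windows truncated at chromosome edges are NA-padded and excluded from
aggregates rather than zero-padded, which would bias edge bins downward.
Strand orientation is the default (upstream means 5' of the gene); a flag
restores unoriented genomic windows. `bin_profile()` sums per-base values in
200-bp bins and orders rows by decreasing total window signal with gene-id
tie-break (determinism for regression tests); `aggregate_profile()` divides
the per-bin column sums by the gene-set size, i.e. the mean profile over
complete rows.

## Accessibility-expression correlation

`region_condition_ratio()` sums depth-normalised signal over the oriented
-1500..+5000 bp window per gene in each condition and forms
`(case + 1) / (control + 1)`; the pseudocount (1 normalised unit) keeps
zero-coverage promoters defined and pulls them to a neutral ratio of 1.
`iterative_threshold_correlation()` then runs 50 cycles, tightening an
absolute-log2FC filter from 0 in steps of 0.1, and reports the Pearson
correlation of log2(ratio) against expression log2FC on each surviving
subset. The log transform of the ratio makes the relation linear under a
multiplicative coupling model; a raw-ratio mode and a signed-filter mode
exist as flags. Correlations on fewer than 3 genes are reported missing.

`binned_track_correlation()` sums both tracks in 1000-bp bins genome-wide
(terminal ragged bins included), pairs bins and reports Pearson r with the
paired values for XY plots. Bins empty in both tracks are retained by
default — two tracks that agree a region is empty do agree — with a
`drop_empty` flag.

## Integration

`assign_peaks_to_promoters()` calls a gene bound when any peak overlaps its
strand-aware promoter window (default TSS +/- 2500 bp; "promoter region" has
no universal definition, so the window is a parameter). One peak may bind
several genes. `intersect_bound_degs()` intersects bound genes with the
FDR-filtered DEG set (default FDR < 0.001, consumed from the upstream DE
table without re-adjustment) and tests direction balance with a one-sided
exact binomial against 0.5. Genes with log2FC exactly 0 are excluded from
both direction counts. The default alternative is enrichment of
*upregulation* — the directional biological hypothesis — because that
one-sided form has exact type-I control at its nominal level, which the
calibration suite verifies; the symmetric `P(X >= max(n_up, n_down))`
variant is available as `alternative = "extreme"` and is roughly a
two-sided test (its size is about twice the nominal level, which is why it
is not the default).

`differential_mark_filter()` reproduces the conjunctive co-filter used for
differential-mark analysis: per region, coverage log2FC (case/control, with
pseudocount, on the depth-normalised scale) for the factor and for a histone
mark, region-to-gene mapping via promoter windows, and retention when both
log2FCs exceed 0.5 and the expression p-value is below 0.05. The full
unfiltered table is also returned for fold-change scatter plots; no
regression model is fitted on top of the filter, as the filter itself is the
reproducible part of that analysis. `hypergeometric_overlap()` and `rpm()`
are the standard upper-tail overlap test and reads-per-million arithmetic.

## Synthetic data: what it emulates, and what it does not

The generators produce, under one global seed (each generator hashes the
seed with its own label, so adding a generator never perturbs another's
stream):

* a genome of i.i.d. bases at a configurable A+T fraction (default 0.59,
  the human genome figure) with non-overlapping, uniformly placed genes and
  fair-coin strands;
* a peak set (default 300 peaks of 500 bp) with a configurable fraction
  centred on TSSs (those genes form the ground-truth bound set), peak
  interiors rewritten to 0.66 A+T, and one concrete instance of an IUPAC
  consensus (default `AAAATAW`) planted per peak at a random offset;
* two-condition coverage: per-base Poisson background (depth 10) with
  promoter windows (TSS +/- 1000 bp, inside both profiling windows) raised
  by an enrichment factor (5) in the control condition and additionally by
  `condition_scale` (4) in the case condition — so the true per-gene
  accessibility effect is 4 at bound genes and 1 elsewhere;
* negative-binomial counts (variance `mu + alpha mu^2`, alpha = 0.1, 3
  replicates, base mean 200) whose true log2 fold change is
  `coupling * log2(accessibility effect)` plus Normal(0, 0.25) noise, with
  moment-estimated log2FCs and Wald-style normal-approximation p-values --
  deliberately simple plumbing, clearly not a DESeq2-class model.

Default sizes put ~1 gene per 20 kb (two 5-Mb chromosomes, 500 genes), so
the -1500..+5000 bp analysis windows rarely swallow a neighbouring gene's
planted promoter; at much higher densities window contamination dilutes the
accessibility-expression correlation, which is a property of the analysis,
not a bug in it. The coupling slope and noise SD are calibration choices,
not literature claims: no effect size for the accessibility-expression
coupling is established, and the defaults are chosen to sit in a regime
where recovery is clear but not trivial.

The generators do not emulate read-level artefacts (fragment-length and Tn5
insertion structure, GC/duplicate bias), mappability, peak-width
heterogeneity, or correlated gene-gene expression. Passing recovery tests
on this synthetic data therefore demonstrates the correctness of the
statistics, not robustness to those real-data artefacts.

## Numerical and procedural choices

* Identical peak/background proportions short-circuit to chi2 = 0, p = 1
  (the chisq machinery is otherwise noisy at the boundary).
* The binomial and hypergeometric tails use `pbinom`/`phyper` upper tails;
  tests pin them to direct pmf summation and exhaustive enumeration.
* Binned row sums are asserted to conserve per-base row sums to 1e-9
  relative; Pearson implementations are pinned to the textbook summation
  formula at 1e-12.
* Heatmap row ordering breaks ties by gene id; all writers emit
  deterministic ordering (genome chromosome order, then start).
* The flat promoter plateau planted by the coverage generator makes the
  aggregate-profile maximum uniform over the plateau bins, so shape tests
  assert the maximum falls inside the planted window rather than in one
  particular bin.

## Problem sizes used by the test-suite and report

The packaged checks run the generators at reduced but structurally
identical sizes (genomes of 0.1-2 Mb for unit and calibration suites; the
default 10-Mb configuration for the end-to-end report), chosen so the whole
suite completes in a few minutes while every statistic stays in its
asymptotic regime: composition tests see >= 1e5 peak bases, recovery suites
use 10 independent seeds, the type-I calibration uses 1000 null datasets
and the null-correlation calibration 200 replicates.

## Known limitations

* The k-mer z-scores rank but do not calibrate; a PWM/EM motif discoverer
  (MEME-class) is out of scope.
* The Jaccard permutation null shuffles only the first set and ignores
  chromatin-state covariates; against a strongly clustered second set the
  p-value is anti-conservative in the way all uniform-placement nulls are.
* The Wald p-values in the synthetic DE table are a generator convenience;
  real analyses should feed a DESeq2/edgeR/limma results table into
  `read_de_table()`.
* `differential_mark_filter()` maps regions to genes only through promoter
  windows; distal regulatory assignments (enhancer-gene links) are not
  attempted.
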