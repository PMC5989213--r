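Package: epihub
Title: Peak Composition, TSS Profiling and Accessibility-Expression
    Integration for ChIP-Seq and ATAC-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistics for regulatory-genomics experiments in which a
    DNA-binding factor is characterised jointly by ChIP-Seq, ATAC-Seq and
    RNA-Seq: A/T base-composition tests of peak sets against the genome
    background, k-mer consensus-motif enrichment with dinucleotide-preserving
    shuffle nulls, peak-to-TSS distance profiles and genomic-region
    classification, interval-set Jaccard similarity with permutation p-values,
    TSS-anchored coverage matrices with binning and aggregate (metagene)
    profiles, iterative-threshold correlation of promoter accessibility ratios
    with expression fold changes, genome-wide binned track correlation, and
    promoter-binding by differential-expression integration (directionality
    and hypergeometric overlap tests). A synthetic-data module generates
    AT-biased genomes, motif-planted peak sets, two-condition coverage tracks
    and negative-binomial expression counts with full ground truth, so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
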