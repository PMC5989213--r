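# Readers, writers and core containers shared by all stages.
#
# Conventions: genomes are Biostrings::DNAStringSet objects (alphabet
# {A,C,G,T,N}); interval sets are GRanges (1-based closed internally; BED and
# bedGraph are converted at the file boundary); gene annotations are plain
# data.frames with a derived TSS column; coverage is a per-chromosome
# run-length list with a cached genome-wide total.

.genome_lengths <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    setNames(width(genome), names(genome))
  } else if (is.numeric(genome) && !is.null(names(genome))) {
    genome
  } else {
    .stopf("`genome` must be a DNAStringSet or a named numeric vector of lengths")
  }
}

.check_genome <- function(genome) {
  if (!is(genome, "DNAStringSet"))
    .stopf("genome must be a DNAStringSet")
  nm <- names(genome)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    .stopf("genome chromosome names must be present and unique")
  freq <- alphabetFrequency(genome, baseOnly = TRUE)
  # baseOnly collapses everything outside A/C/G/T into "other"; only N allowed
  other <- sum(freq[, "other"])
  nN <- sum(vapply(seq_along(genome), function(i)
    countPattern("N", genome[[i]], fixed = TRUE), 0L))
  if (other > nN)
    .stopf("genome contains letters outside {A,C,G,T,N}")
  invisible(genome)
}

#' Read and write genome sequences (FASTA)
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] that validate the `{A,C,G,T,N}` alphabet
#' and unique chromosome names.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  .check_genome(g)
  g
}

#' @rdname read_genome
#' @param genome A named `DNAStringSet`.
#' @export
write_genome <- function(genome, path) {
  .check_genome(genome)
  writeXStringSet(genome, path)
  invisible(path)
}

# ---- BED ------------------------------------------------------------------

.validate_intervals <- function(chrom, start1, end1, genome = NULL, what = "interval") {
  if (!is.null(genome)) {
    lens <- .genome_lengths(genome)
    unknown <- setdiff(unique(chrom), names(lens))
    if (length(unknown))
      .stopf("%s set refers to unknown chromosome(s): %s", what,
             paste(unknown, collapse = ", "))
    over <- which(end1 > lens[chrom] | start1 < 1)
    if (length(over))
      .stopf("%s %d (%s:%d-%d) exceeds chromosome bounds", what, over[1],
             chrom[over[1]], start1[over[1]] - 1L, end1[over[1]])
  }
  invisible(TRUE)
}

.as_sorted_granges <- function(chrom, start1, end1, score = NULL, genome = NULL) {
  lev <- if (!is.null(genome)) names(.genome_lengths(genome)) else unique(chrom)
  gr <- GRanges(factor(chrom, levels = lev), IRanges(start1, end1))
  if (!is.null(genome)) seqlengths(gr) <- .genome_lengths(genome)[lev]
  if (!is.null(score)) mcols(gr)$score <- score
  sort(gr, ignore.strand = TRUE)
}

#' Read and write interval sets (BED)
#'
#' BED coordinates (0-based half-open) are converted to the internal 1-based
#' closed representation on input and back on output. Round trips are lossless
#' on `(chrom, start, end, score)`.
#'
#' @param path Path to a tab-separated BED3+ file.
#' @param genome Optional genome (`DNAStringSet` or named lengths) used to
#'   validate chromosome names and bounds and to fix chromosome order.
#' @return A sorted [GenomicRanges::GRanges] (with a `score` metadata column
#'   when the file has 5+ columns).
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   quote = "", stringsAsFactors = FALSE)
  if (ncol(df) < 3) .stopf("BED file %s has fewer than 3 columns", path)
  chrom <- as.character(df[[1]])
  start0 <- df[[2]]; end0 <- df[[3]]
  if (!is.numeric(start0) || !is.numeric(end0) || any(start0 < 0))
    .stopf("BED file %s: coordinates must be non-negative integers", path)
  bad <- which(start0 >= end0)
  if (length(bad))
    .stopf("malformed interval on line %d of %s: start %d >= end %d",
           bad[1], path, start0[bad[1]], end0[bad[1]])
  .validate_intervals(chrom, start0 + 1L, end0, genome, "BED interval")
  score <- if (ncol(df) >= 5 && is.numeric(df[[5]])) df[[5]] else NULL
  .as_sorted_granges(chrom, as.integer(start0) + 1L, as.integer(end0), score, genome)
}

#' @rdname read_bed
#' @param intervals A `GRanges`.
#' @export
write_bed <- function(intervals, path) {
  gr <- sort(intervals, ignore.strand = TRUE)
  has_score <- "score" %in% names(mcols(gr))
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (has_score) {
    df$name <- "."
    df$score <- mcols(gr)$score
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- coverage tracks ------------------------------------------------------

#' Coverage track container
#'
#' A per-chromosome run-length encoded vector of non-negative per-base signal
#' plus a cached genome-wide total (used as the normalisation constant by the
#' profiling and ratio stages).
#'
#' @param cov A named list of numeric vectors or [S4Vectors::Rle] objects, one
#'   per chromosome, in genome order.
#' @return An object of class `CoverageTrack` with elements `cov` (list of
#'   `Rle`) and `total`.
#' @export
coverage_track <- function(cov) {
  if (!length(cov) || is.null(names(cov)) || anyDuplicated(names(cov)))
    .stopf("cov must be a non-empty uniquely named list")
  cov <- lapply(cov, function(x) {
    r <- if (is(x, "Rle")) x else Rle(as.numeric(x))
    if (any(runValue(r) < 0) || any(!is.finite(runValue(r))))
      .stopf("coverage values must be finite and >= 0")
    r
  })
  total <- sum(vapply(cov, function(r) sum(as.numeric(runValue(r)) * runLength(r)), 0))
  structure(list(cov = cov, total = total), class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack:", length(x$cov), "chromosome(s),",
      format(sum(chrom_lengths(x))), "bp, total signal", format(x$total), "\n")
  invisible(x)
}

#' @rdname coverage_track
#' @param track A `CoverageTrack`.
#' @export
chrom_lengths <- function(track) {
  vapply(track$cov, length, 0L)
}

#' @rdname coverage_track
#' @export
coverage_total <- function(track) track$total

# Extract the per-base window [lo, hi] (1-based closed) of one chromosome.
.track_window <- function(track, chrom, lo, hi) {
  as.numeric(window(track$cov[[chrom]], lo, hi))
}

.track_window_sum <- function(track, chrom, lo, hi) {
  r <- track$cov[[chrom]]
  sum(as.numeric(window(r, lo, hi)))
}

#' Read and write coverage tracks (bedGraph)
#'
#' bedGraph runs are expanded to per-base signal; bases not covered by any
#' record are zero. Overlapping records are an error (their sum would be
#' ambiguous). The writer emits run-length merged records for non-zero runs,
#' so write/read round trips reproduce the per-base arrays exactly.
#'
#' @param path Path to a 4-column bedGraph file.
#' @param genome Genome (`DNAStringSet` or named lengths); required, as it
#'   fixes chromosome lengths.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, genome) {
  lens <- .genome_lengths(genome)
  if (!file.exists(path)) .stopf("no such file: %s", path)
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   quote = "", stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "value"))
  if (any(df$start >= df$end))
    .stopf("bedGraph %s: malformed record (start >= end)", path)
  if (any(!is.finite(df$value)) || any(df$value < 0))
    .stopf("bedGraph %s: values must be finite and >= 0", path)
  .validate_intervals(df$chrom, df$start + 1L, df$end, lens, "bedGraph record")
  cov <- lapply(names(lens), function(ch) {
    L <- unname(lens[[ch]])
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (!nrow(sub)) return(Rle(0, L))
    sub <- sub[order(sub$start), , drop = FALSE]
    n <- nrow(sub)
    if (n > 1 && any(sub$start[-1] < sub$end[-n]))
      .stopf("bedGraph %s: overlapping records on %s", path, ch)
    gap_before <- sub$start - c(0L, sub$end[-n])
    vals <- as.numeric(rbind(0, sub$value))
    lensv <- as.integer(rbind(gap_before, sub$end - sub$start))
    vals <- c(vals, 0); lensv <- c(lensv, L - sub$end[n])
    keep <- lensv > 0L
    Rle(vals[keep], lensv[keep])
  })
  names(cov) <- names(lens)
  coverage_track(cov)
}

#' @rdname read_bedgraph
#' @param track A `CoverageTrack`.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$cov)) {
    r <- track$cov[[ch]]
    rl <- runLength(r); rv <- runValue(r)
    ends <- cumsum(as.numeric(rl))
    starts <- ends - rl  # already 0-based
    keep <- rv != 0
    if (!any(keep)) next
    lines <- sprintf("%s\t%d\t%d\t%s", ch, as.integer(starts[keep]),
                     as.integer(ends[keep]),
                     vapply(rv[keep], function(v)
                       format(v, digits = 15, scientific = FALSE, trim = TRUE), ""))
    writeLines(lines, con)
  }
  invisible(path)
}

# ---- gene annotation ------------------------------------------------------

#' Gene annotation table
#'
#' Builds the per-gene record used by every TSS-anchored stage: id,
#' chromosome, strand, 1-based closed span and the derived TSS (first base of
#' the span on `+`, last base on `-`).
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param chrom,strand,start,end Per-gene location (strand in `+`/`-`).
#' @param genome Optional genome for bounds validation.
#' @return A `data.frame` of class `gene_annotation` with a `tss` column.
#' @export
gene_annotation <- function(gene_id, chrom, strand, start, end, genome = NULL) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    .stopf("duplicate gene_id(s): %s",
           paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (any(is.na(strand)) || !all(strand %in% c("+", "-")))
    .stopf("strand must be '+' or '-' for every gene")
  if (any(start > end)) .stopf("gene start must be <= end")
  .validate_intervals(as.character(chrom), start, end, genome, "gene")
  df <- data.frame(gene_id = gene_id, chrom = as.character(chrom),
                   strand = as.character(strand),
                   start = as.integer(start), end = as.integer(end),
                   tss = as.integer(ifelse(strand == "+", start, end)),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read a gene annotation (BED6 or GTF)
#'
#' BED inputs use column 4 as the gene id and column 6 as strand; GTF inputs
#' keep only `gene` feature rows and take the id from the `gene_id` attribute.
#' GTF coordinates (1-based closed) map directly onto the internal model; BED
#' starts are shifted by one.
#'
#' @param path Annotation file path.
#' @param format `"bed"` or `"gtf"` (default guessed from the extension).
#' @param genome Optional genome for validation.
#' @return A [gene_annotation()].
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gtf"),
                                 genome = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gtf$|\\.gff$", path, ignore.case = TRUE)) "gtf" else "bed"
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   quote = "", stringsAsFactors = FALSE)
  if (format == "bed") {
    if (ncol(df) < 6) .stopf("BED annotation needs 6 columns (id in 4, strand in 6)")
    gene_annotation(df[[4]], df[[1]], df[[6]], df[[2]] + 1L, df[[3]], genome)
  } else {
    df <- df[df[[3]] == "gene", , drop = FALSE]
    if (!nrow(df)) .stopf("GTF %s contains no 'gene' feature rows", path)
    ids <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", df[[9]])
    gene_annotation(ids, df[[1]], df[[7]], df[[4]], df[[5]], genome)
  }
}

#' @rdname read_gene_annotation
#' @param annotation A `gene_annotation`.
#' @export
write_gene_annotation_gtf <- function(annotation, path) {
  lines <- sprintf('%s\tepihub\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                   annotation$chrom, annotation$start, annotation$end,
                   annotation$strand, annotation$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Strand-aware promoter windows
#'
#' For a `+` gene the window is `[tss - upstream, tss + downstream]`; for a
#' `-` gene it is mirrored. Windows are clamped to chromosome bounds when a
#' genome is supplied.
#'
#' @param annotation A [gene_annotation()].
#' @param upstream,downstream Window extents in bp (both `>= 0`).
#' @param genome Optional genome for clamping.
#' @return A `GRanges` with a `gene_id` metadata column.
#' @export
promoter_ranges <- function(annotation, upstream = 2000, downstream = 500,
                            genome = NULL) {
  plus <- annotation$strand == "+"
  lo <- ifelse(plus, annotation$tss - upstream, annotation$tss - downstream)
  hi <- ifelse(plus, annotation$tss + downstream, annotation$tss + upstream)
  lo <- pmax(lo, 1L)
  if (!is.null(genome)) {
    lens <- .genome_lengths(genome)
    hi <- pmin(hi, unname(lens[annotation$chrom]))
  }
  gr <- GRanges(annotation$chrom, IRanges(lo, hi), strand = annotation$strand)
  mcols(gr)$gene_id <- annotation$gene_id
  gr
}

# ---- differential-expression tables --------------------------------------

#' Read a differential-expression table
#'
#' Tab-separated with a header; column names are configurable so tables from
#' any upstream caller (e.g. a DESeq2 results export) can be consumed as-is.
#'
#' @param path TSV file path.
#' @param columns Named character vector mapping the internal fields
#'   `gene`, `log2fc`, `pvalue`, `fdr` (and optionally `base_mean`) to the
#'   file's column names.
#' @return A `data.frame` of class `de_table` with columns `gene_id`,
#'   `log2fc`, `pvalue`, `fdr`, `base_mean`.
#' @export
read_de_table <- function(path,
                          columns = c(gene = "gene", log2fc = "log2FC",
                                      pvalue = "p", fdr = "FDR",
                                      base_mean = "baseMean")) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "log2fc", "pvalue", "fdr")
  miss <- setdiff(columns[need], names(df))
  if (length(miss))
    .stopf("DE table %s lacks column(s): %s", path, paste(miss, collapse = ", "))
  bm <- if (!is.na(columns["base_mean"]) && columns["base_mean"] %in% names(df))
    df[[columns["base_mean"]]] else NA_real_
  de_table(df[[columns["gene"]]], df[[columns["log2fc"]]],
           df[[columns["pvalue"]]], df[[columns["fdr"]]], bm)
}

#' @rdname read_de_table
#' @param gene_id,log2fc,pvalue,fdr,base_mean Per-gene vectors.
#' @export
de_table <- function(gene_id, log2fc, pvalue, fdr, base_mean = NA_real_) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) .stopf("duplicate gene_id in DE table")
  ok <- function(p) all(is.na(p) | (p >= 0 & p <= 1))
  if (!ok(pvalue) || !ok(fdr)) .stopf("p-values and FDR must lie in [0, 1]")
  df <- data.frame(gene_id = gene_id, log2fc = as.numeric(log2fc),
                   pvalue = as.numeric(pvalue), fdr = as.numeric(fdr),
                   base_mean = as.numeric(base_mean), stringsAsFactors = FALSE)
  class(df) <- c("de_table", "data.frame")
  df
}

#' @rdname read_de_table
#' @param de A `de_table`.
#' @export
write_de_table <- function(de, path) {
  out <- data.frame(gene = de$gene_id, log2FC = de$log2fc, p = de$pvalue,
                    FDR = de$fdr, baseMean = de$base_mean)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- sequences under intervals -------------------------------------------

#' Extract the genome sequence under each interval
#'
#' @param genome A `DNAStringSet`.
#' @param intervals A `GRanges` within genome bounds.
#' @return A `DNAStringSet`, one entry per interval, in input order.
#' @export
interval_seqs <- function(genome, intervals) {
  .validate_intervals(as.character(seqnames(intervals)), start(intervals),
                      end(intervals), genome, "interval")
  out <- vector("list", length(intervals))
  chs <- as.character(seqnames(intervals))
  for (ch in unique(chs)) {
    idx <- which(chs == ch)
    v <- Views(genome[[ch]], start(intervals)[idx], end(intervals)[idx])
    out[idx] <- as.list(as(v, "DNAStringSet"))
  }
  do.call(c, lapply(out, DNAStringSet))
}
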