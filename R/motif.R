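# Consensus-motif tooling: k-mer enrichment against a dinucleotide-preserving
# shuffle null, and IUPAC consensus scanning.

# Altschul-Erikson dinucleotide-preserving shuffle on an integer-coded
# sequence (codes 1..K). Picks a random Eulerian path in the order-1 de
# Bruijn graph: choose a random "last edge" per vertex, accept only
# arborescences into the final vertex, then permute the remaining edges and
# walk the path.
.dinuc_shuffle_codes <- function(x, K) {
  n <- length(x)
  if (n < 4) return(x)
  from <- x[-n]
  to <- x[-1]
  foll <- lapply(seq_len(K), function(v) to[from == v])
  final <- x[n]
  present <- which(vapply(foll, length, 0L) > 0)
  nonfinal <- setdiff(present, final)
  lastpick <- integer(K)
  if (length(nonfinal)) {
    repeat {
      for (v in nonfinal) {
        f <- foll[[v]]
        lastpick[v] <- f[sample.int(length(f), 1L)]
      }
      ok <- TRUE
      for (v in nonfinal) {
        cur <- v
        for (step in seq_len(K + 1L)) {
          cur <- lastpick[cur]
          if (cur == final) break
        }
        if (cur != final) { ok <- FALSE; break }
      }
      if (ok) break
    }
  }
  for (v in present) {
    f <- foll[[v]]
    if (v %in% nonfinal) {
      f <- f[-match(lastpick[v], f)]
      foll[[v]] <- c(if (length(f)) f[sample.int(length(f))], lastpick[v])
    } else {
      foll[[v]] <- f[sample.int(length(f))]
    }
  }
  out <- integer(n)
  out[1] <- x[1]
  ptr <- rep(1L, K)
  cur <- x[1]
  for (i in 2:n) {
    nxt <- foll[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  out
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Shuffles each sequence while preserving its exact dinucleotide counts
#' (Altschul-Erikson Eulerian-path shuffle). Used as the null model for
#' [kmer_motif_enrichment()]; exposed for building null controls.
#'
#' @param seqs A `DNAStringSet` or character vector.
#' @param seed Optional integer seed.
#' @return A `DNAStringSet` of shuffled sequences.
#' @export
dinucleotide_shuffle <- function(seqs, seed = NULL) {
  if (!is.null(seed)) set.seed(.substream(seed, "dinuc-shuffle"))
  ss <- as.character(seqs)
  alpha <- c("A", "C", "G", "T", "N")
  out <- vapply(ss, function(s) {
    codes <- match(strsplit(s, "")[[1]], alpha)
    if (anyNA(codes)) .stopf("sequence contains letters outside {A,C,G,T,N}")
    paste(alpha[.dinuc_shuffle_codes(codes, 5L)], collapse = "")
  }, "", USE.NAMES = FALSE)
  DNAStringSet(out)
}

# Pool each k-mer with its reverse complement under the lexicographic-min
# canonical representative.
.canonical_counts <- function(seqs, k) {
  cnt <- colSums(oligonucleotideFrequency(seqs, k))
  kmers <- names(cnt)
  rc <- as.character(reverseComplement(DNAStringSet(kmers)))
  canon <- ifelse(kmers <= rc, kmers, rc)
  tapply(cnt, canon, sum)
}

#' k-mer enrichment in peak sequences
#'
#' Counts every canonical k-mer (a k-mer pooled with its reverse complement)
#' in the peak sequences and compares the observed counts with their mean and
#' spread across `n_shuffles` dinucleotide-preserving shuffles of the same
#' sequences. The z-score denominator is the empirical shuffle SD floored at
#' `sqrt(mean + 1)` (a Poisson-scale floor that keeps rare k-mers from
#' producing unstable scores). Dinucleotide-preserving nulls matter here
#' because AT-rich sequence makes mononucleotide backgrounds anticonservative.
#'
#' @param peaks A non-empty `GRanges`.
#' @param genome A `DNAStringSet`.
#' @param k K-mer length (>= 4; default 7).
#' @param n_shuffles Number of shuffled replicates (default 10).
#' @param seed Integer seed for the shuffles.
#' @return A `data.frame` of class `kmer_enrichment` with columns `kmer`
#'   (canonical), `observed`, `expected`, `sd`, `z`, sorted by decreasing `z`
#'   (ties broken lexicographically).
#' @export
kmer_motif_enrichment <- function(peaks, genome, k = 7, n_shuffles = 10,
                                  seed = 1) {
  if (k < 4) .stopf("k must be >= 4")
  if (!length(peaks)) .stopf("empty peak set")
  seqs <- interval_seqs(genome, peaks)
  if (min(width(seqs)) < k) .stopf("k exceeds the shortest peak length")
  obs <- .canonical_counts(seqs, k)
  set.seed(.substream(seed, "kmer-shuffles"))
  null <- matrix(0, nrow = n_shuffles, ncol = length(obs))
  for (s in seq_len(n_shuffles)) {
    null[s, ] <- .canonical_counts(dinucleotide_shuffle(seqs), k)
  }
  expd <- colMeans(null)
  sds <- apply(null, 2, sd)
  z <- (as.numeric(obs) - expd) / pmax(sds, sqrt(expd + 1))
  out <- data.frame(kmer = names(obs), observed = as.integer(obs),
                    expected = expd, sd = sds, z = z,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$z, out$kmer), ]
  rownames(out) <- NULL
  attr(out, "k") <- k
  attr(out, "n_shuffles") <- n_shuffles
  class(out) <- c("kmer_enrichment", "data.frame")
  out
}

#' Convert an IUPAC consensus to a regular expression
#'
#' Each degenerate code becomes a character class (`W` -> `[AT]`), anchored
#' at both ends; useful for asking whether a concrete k-mer matches a
#' consensus (in either orientation, see `either_strand`).
#'
#' @param pattern IUPAC consensus string.
#' @return A regex string.
#' @export
iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_CODE_MAP))
  if (length(bad))
    .stopf("invalid IUPAC code(s) in pattern: %s", paste(bad, collapse = ", "))
  body <- paste(vapply(chars, function(ch) {
    opts <- IUPAC_CODE_MAP[[ch]]
    if (nchar(opts) == 1) opts else paste0("[", opts, "]")
  }, ""), collapse = "")
  paste0("^", body, "$")
}

#' Does a k-mer match an IUPAC consensus on either strand?
#'
#' @param kmer Concrete DNA string(s).
#' @param pattern IUPAC consensus of the same length.
#' @return Logical vector.
#' @export
matches_consensus <- function(kmer, pattern) {
  fwd <- iupac_regex(pattern)
  rev <- iupac_regex(as.character(reverseComplement(DNAString(toupper(pattern)))))
  grepl(fwd, toupper(kmer)) | grepl(rev, toupper(kmer))
}

#' Scan a genome for an IUPAC consensus
#'
#' Reports all match positions on both strands (1-based closed `GRanges`
#' with strand), deduplicated and sorted; restricted to `regions` when given.
#'
#' @param genome A `DNAStringSet`.
#' @param pattern An IUPAC consensus string (e.g. `"AAAATAW"`).
#' @param regions Optional `GRanges`; only matches falling entirely inside
#'   are reported.
#' @return A sorted `GRanges` of matches with strand.
#' @export
scan_consensus <- function(genome, pattern, regions = NULL) {
  pattern <- toupper(pattern)
  bad <- setdiff(strsplit(pattern, "")[[1]], names(IUPAC_CODE_MAP))
  if (length(bad))
    .stopf("invalid IUPAC code(s) in pattern: %s", paste(bad, collapse = ", "))
  hit_gr <- function(pat, strand_label) {
    m <- vmatchPattern(pat, genome, fixed = FALSE)
    chs <- rep(names(genome), vapply(m, length, 0L))
    ir <- unlist(IRangesList(m), use.names = FALSE)
    GRanges(factor(chs, levels = names(genome)), ir, strand = strand_label)
  }
  fwd <- hit_gr(pattern, "+")
  rcpat <- as.character(reverseComplement(DNAString(pattern)))
  rev <- hit_gr(rcpat, "-")
  hits <- c(fwd, rev)
  if (!is.null(regions) && length(hits))
    hits <- hits[overlapsAny(hits, regions, type = "within",
                             ignore.strand = TRUE)]
  sort(unique(hits), ignore.strand = TRUE)
}
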