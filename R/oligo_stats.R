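# Oligonucleotide counting, frequency aggregation, reference-word selection
# and genome composition statistics (GC fraction, HIP1-like repeat density).
#
# Words are indexed in the canonical lexicographic order over {A,C,G,T} used
# by Biostrings::oligonucleotideFrequency(), so positions are comparable
# across genes, gene sets and runs.

#' Count overlapping k-mers in a single sequence
#'
#' Every overlapping window of length `k` consisting only of `A`, `C`, `G`,
#' `T` is counted once.  Windows containing `N` (or any ambiguity code) are
#' skipped and reported in the skipped-window tally; they still count toward
#' the effective window number `length - k + 1`.
#'
#' @param sequence A character string, [Biostrings::DNAString], or single
#'   element of a `DNAStringSet`.
#' @param k Word length (`k >= 1`).
#' @return A list with `counts` (named integer vector over the observed
#'   words), `windows` (effective window count, `max(0, length - k + 1)`) and
#'   `skipped` (windows not counted because of ambiguity codes).
#' @export
count_kmers <- function(sequence, k) {
  stopifnot(k >= 1)
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  if (methods::is(sequence, "DNAStringSet")) {
    stopifnot(length(sequence) == 1)
    sequence <- sequence[[1]]
  }
  n <- length(sequence)
  windows <- max(0L, n - as.integer(k) + 1L)
  if (windows == 0L) {
    return(list(counts = integer(0), windows = 0L, skipped = 0L))
  }
  v <- Biostrings::oligonucleotideFrequency(sequence, width = k)
  counted <- sum(v)
  list(counts = v[v > 0L], windows = windows,
       skipped = windows - as.integer(counted))
}

# Per-gene sparse octamer profiles used by the covariance scoring engine.
# Returns a list per gene: idx (1-based positions in the canonical 4^k
# order), counts, windows, countable (windows counted, i.e. without
# ambiguity).
kmer_profiles <- function(genes, k) {
  lapply(seq_along(genes), function(i) {
    s <- genes[[i]]
    windows <- max(0L, length(s) - as.integer(k) + 1L)
    if (windows == 0L) {
      return(list(idx = integer(0), counts = integer(0),
                  windows = 0L, countable = 0L))
    }
    v <- Biostrings::oligonucleotideFrequency(s, width = k)
    idx <- which(v > 0L)
    list(idx = idx, counts = unname(v[idx]), windows = windows,
         countable = as.integer(sum(v)))
  })
}

#' Aggregate k-mer frequencies over a gene set
#'
#' The frequency of each word is the sum of its counts across all genes
#' divided by the total effective length, where each gene of length `L >= k`
#' contributes `L - k + 1` windows.  Genes shorter than `k` contribute
#' nothing.  Windows containing ambiguity codes are skipped from the counts
#' but the denominator is not reduced, so the frequencies sum to at most 1
#' (exactly 1 when nothing was skipped).
#'
#' @param genes A [Biostrings::DNAStringSet] of gene sequences.
#' @param k Word length; the standard analysis uses octamers (`k = 8`).
#' @param both_strands If `TRUE`, counts from the reverse complement of each
#'   gene are added and the effective length doubled.  The default scores
#'   the supplied (coding) strand only.
#' @param source Optional label recording which gene set the frequencies
#'   came from (e.g. `"core"` or `"all"`).
#' @return An object of class `oligo_freq_set`: a list with `k`, `counts`
#'   (full named integer vector over all `4^k` words), `frequencies`,
#'   `total_effective_length`, `skipped_windows` and `source`.
#' @export
aggregate_frequencies <- function(genes, k = 8, both_strands = FALSE,
                                  source = "all") {
  stopifnot(k >= 1)
  widths <- Biostrings::width(genes)
  usable <- widths >= k
  if (!any(usable)) stop("no countable windows: all genes shorter than k")
  gs <- genes[usable]
  counts <- Biostrings::oligonucleotideFrequency(gs, width = k,
                                                 simplify.as = "collapsed")
  eff <- sum(widths[usable] - k + 1)
  if (both_strands) {
    rc <- Biostrings::reverseComplement(gs)
    counts <- counts + Biostrings::oligonucleotideFrequency(
      rc, width = k, simplify.as = "collapsed")
    eff <- 2 * eff
  }
  structure(list(
    k = as.integer(k),
    counts = counts,
    frequencies = counts / eff,
    total_effective_length = eff,
    skipped_windows = eff - sum(counts),
    source = source
  ), class = "oligo_freq_set")
}

#' @export
print.oligo_freq_set <- function(x, ...) {
  cat(sprintf(
    "oligo_freq_set: k=%d, source=%s, %d windows (%d skipped), %d/%d words observed\n",
    x$k, x$source, x$total_effective_length, x$skipped_windows,
    sum(x$counts > 0), length(x$counts)))
  invisible(x)
}

#' Select the reference oligonucleotides (lowest-frequency words)
#'
#' Words are sorted by ascending frequency (ties broken by lexicographic
#' order) and the lowest `floor(fraction * 4^k)` are selected as the
#' reference oligonucleotides.  When more words than that have zero counts,
#' all zero-count words are selected instead, so that no observed word is
#' arbitrarily split off a tie at frequency zero.  The reference frequencies
#' `f_R` cover the selected members individually plus one pooled category for
#' all other words combined.
#'
#' @param freqs An `oligo_freq_set` from [aggregate_frequencies()].
#' @param fraction Selection fraction in `(0, 1]`; the standard method uses
#'   the least frequent 20 percent.
#' @param zero_override Apply the all-zero-count-words rule described above
#'   (default `TRUE`).
#' @return An object of class `ref_oligo_set`: a list with `k`, `members`
#'   (selected words), `member_idx` (positions in canonical word order),
#'   `fraction`, `f_R` (reference frequencies of the members, canonical
#'   order), `f_R_other` (pooled frequency of all other words),
#'   `n_categories` (`length(members) + 1`) and `zero_override_applied`.
#' @export
select_reference_oligos <- function(freqs, fraction = 0.20,
                                    zero_override = TRUE) {
  stopifnot(inherits(freqs, "oligo_freq_set"),
            fraction > 0, fraction <= 1)
  f <- freqs$frequencies
  nw <- length(f)
  target <- floor(fraction * nw)
  n_zero <- sum(f == 0)
  override <- zero_override && n_zero > target
  if (override) {
    member_idx <- unname(which(f == 0))
  } else {
    # order() is stable, so equal frequencies fall back to canonical
    # (lexicographic) word order.
    member_idx <- sort(order(f)[seq_len(target)])
  }
  f_R <- unname(f[member_idx])
  structure(list(
    k = freqs$k,
    members = names(f)[member_idx],
    member_idx = member_idx,
    fraction = fraction,
    f_R = f_R,
    f_R_other = sum(f) - sum(f_R),
    n_categories = length(member_idx) + 1L,
    zero_override_applied = override,
    source = freqs$source
  ), class = "ref_oligo_set")
}

#' @export
print.ref_oligo_set <- function(x, ...) {
  cat(sprintf(
    "ref_oligo_set: k=%d, %d member words (fraction %.2f%s), f_R(other)=%.4f\n",
    x$k, length(x$member_idx), x$fraction,
    if (x$zero_override_applied) ", zero-count override" else "",
    x$f_R_other))
  invisible(x)
}

#' GC fraction of sequences
#'
#' `(G + C) / (A + C + G + T)`; `N` and other ambiguity codes are excluded
#' from both numerator and denominator.  For a `DNAStringSet` the fraction is
#' computed over the pooled counts of all elements.
#'
#' @param x A character string, `DNAString`, or `DNAStringSet`.
#' @return GC fraction in `[0, 1]`.
#' @export
gc_fraction <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (methods::is(x, "DNAString")) x <- Biostrings::DNAStringSet(x)
  af <- Biostrings::alphabetFrequency(x, baseOnly = TRUE)
  if (is.null(dim(af))) af <- matrix(af, nrow = 1, dimnames = list(NULL, names(af)))
  tot <- colSums(af[, c("A", "C", "G", "T"), drop = FALSE])
  denom <- sum(tot)
  if (denom == 0) stop("no countable (A/C/G/T) nucleotides")
  unname((tot[["G"]] + tot[["C"]]) / denom)
}

#' Density of a repeat motif per million nucleotides
#'
#' Counts overlapping occurrences of `motif` on the given strand and scales
#' to sites per 1e6 nt of sequence.  The default motif is the highly iterated
#' palindrome HIP1 (`GCGATCGC`), which is its own reverse complement, so one
#' strand suffices; for non-palindromic motifs set `both_strands = TRUE` to
#' add occurrences on the reverse complement.
#'
#' @param genome A `DNAString`, `DNAStringSet` (summed over elements), or
#'   character string.
#' @param motif The motif to count.
#' @param both_strands Also count the reverse-complement strand.
#' @return Occurrences per 1e6 nt.
#' @export
hip1_density <- function(genome, motif = "GCGATCGC", both_strands = FALSE) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (methods::is(genome, "DNAString")) genome <- Biostrings::DNAStringSet(genome)
  pat <- Biostrings::DNAString(motif)
  total_nt <- sum(Biostrings::width(genome))
  if (total_nt < length(pat)) stop("sequence shorter than motif")
  n <- sum(Biostrings::vcountPattern(pat, genome))
  if (both_strands) {
    n <- n + sum(Biostrings::vcountPattern(
      Biostrings::reverseComplement(pat), genome))
  }
  n * 1e6 / total_nt
}

#' Export an oligomer frequency set as TSV
#'
#' Writes a header block (`# k=`, `# source=`, `# total_effective_length=`)
#' followed by `kmer<TAB>count<TAB>frequency` rows for all words with
#' non-zero counts.
#'
#' @param freqs An `oligo_freq_set`.
#' @param path Output path.
#' @param all_words Write all `4^k` rows instead of only observed words.
#' @return `path`, invisibly.
#' @export
export_frequencies <- function(freqs, path, all_words = FALSE) {
  stopifnot(inherits(freqs, "oligo_freq_set"))
  keep <- if (all_words) seq_along(freqs$counts) else which(freqs$counts > 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# k=%d", freqs$k),
    sprintf("# source=%s", freqs$source),
    sprintf("# total_effective_length=%d", freqs$total_effective_length),
    "kmer\tcount\tfrequency"
  ), con)
  utils::write.table(
    data.frame(kmer = names(freqs$counts)[keep],
               count = unname(freqs$counts[keep]),
               frequency = unname(freqs$frequencies[keep])),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Import an oligomer frequency set written by [export_frequencies()]
#'
#' @param path Path to the TSV file.
#' @return An `oligo_freq_set`.
#' @export
import_frequencies <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getval <- function(key) sub(paste0("^# ", key, "="), "", grep(
    paste0("^# ", key, "="), hdr, value = TRUE)[1])
  k <- as.integer(getval("k"))
  eff <- as.integer(getval("total_effective_length"))
  src <- getval("source")
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                           stringsAsFactors = FALSE)
  counts <- integer(4^k)
  names(counts) <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  counts[tab$kmer] <- tab$count
  structure(list(
    k = k, counts = counts, frequencies = counts / eff,
    total_effective_length = eff,
    skipped_windows = eff - sum(counts), source = src
  ), class = "oligo_freq_set")
}
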