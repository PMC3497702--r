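# Shared fixtures, built in code.  Benchmark bundles are cached per test run
# because several files probe different facets of the same experiment.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, maker) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- maker()
  .fixture_cache[[name]]
}

# A named DNAStringSet with metadata, from a named character vector.
make_genes <- function(seqs, genome_id = "test") {
  x <- Biostrings::DNAStringSet(seqs)
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(
    genome_id = rep(genome_id, length(x)),
    description = rep("", length(x)))
  x
}

# Write a FASTA text fixture and return its path.
write_fasta_fixture <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# Small benchmark for plumbing tests: no need for scoring power.
small_bundle <- function() {
  cached_fixture("small_bundle", function() {
    make_benchmark_pair(
      synthetic_spec(90, gc = 0.47, length_mean = 450, length_sd = 90,
                     length_min = 150, genome_id = "tgt",
                     profile_seed = 11, seed = 1),
      synthetic_spec(60, gc = 0.32, length_mean = 450, length_sd = 90,
                     length_min = 150, genome_id = "don",
                     profile_seed = 22, seed = 2),
      core_fraction = 0.30, p = 0.10, seed = 3)
  })
}

# Standard-scale benchmark emulating the study conditions: a core set of
# paper scale (200 genes), a 400-gene calibration set, 3% seeding.
std_bundle <- function(donor_gc, name = paste0("std_", donor_gc)) {
  cached_fixture(name, function() {
    make_benchmark_pair(
      synthetic_spec(600, gc = 0.50, genome_id = "tgt",
                     profile_seed = 101, seed = 1),
      synthetic_spec(200, gc = donor_gc, genome_id = "don",
                     profile_seed = 202, seed = 2),
      core_fraction = 1 / 3, p = 0.03, seed = 5)
  })
}

# Canonical form for comparing k-mer count mappings: drop zeros, sort by
# word.
sort_named <- function(x) {
  x <- x[x > 0]
  if (length(x) == 0) return(stats::setNames(integer(0), character(0)))
  x[base::order(names(x))]
}

# Character-by-character sliding-window oracle for k-mer counting.
naive_count_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) {
    return(list(counts = stats::setNames(integer(0), character(0)),
                windows = 0L, skipped = 0L))
  }
  subs <- substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
  ok <- !grepl("[^ACGT]", subs)
  counts <- table(subs[ok])
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = sort_named(counts),
       windows = n - k + 1L,
       skipped = sum(!ok))
}

# Random DNA string that may contain Ns.
random_dna <- function(n, p_n = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)),
        collapse = "")
}

# Enumeration oracle for maximal discrimination: evaluates the
# discrimination just below and just above every observed score, covering
# every achievable flag set.
oracle_max_disc <- function(foreign, native, orientation, eps = 1e-9) {
  u <- sort(unique(c(foreign, native)))
  cuts <- sort(c(u - eps, u + eps))
  if (orientation == "low") {
    max(vapply(cuts, function(cut) {
      mean(foreign < cut) - mean(native < cut)
    }, numeric(1)))
  } else {
    max(vapply(cuts, function(cut) {
      mean(foreign > cut) - mean(native > cut)
    }, numeric(1)))
  }
}
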