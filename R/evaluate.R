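# End-to-end evaluation harness: score a seeded benchmark by every method,
# compute thresholds and discrimination, and run the contamination and
# frequency-slice sweeps used to probe each method's failure modes.

#' Evaluate all scoring methods on a seeded benchmark
#'
#' Scores the seeded genome (native plus test-foreign genes) by the
#' requested methods, fixes each method's threshold at the target
#' false-positive rate on the test-native genes, and reports discrimination
#' at that threshold together with the maximal discrimination over all
#' thresholds.
#'
#' Reference pools follow each method's definition: CGS trains only on the
#' core genes, so seeded genes cannot poison it; W8 trains on all genes of
#' the seeded genome; the modified W8 variant (`"W8_modified"`) trains on
#' native genes only and restricts the reference to the same low-frequency
#' slice as CGS, so the only remaining difference from CGS is the use of all
#' native genes rather than core genes; GC takes its expected GC over all
#' genes of the seeded genome; codon bias resolves its highly-expressed
#' reference classes from gene descriptions and its average-gene usage from
#' the seeded genome.
#'
#' @param bundle A `benchmark_pair` from [make_benchmark_pair()], or any
#'   list with `seeded`, `core_ids`, `test_native_ids`, `foreign_ids`.
#' @param methods Methods to run, a subset of
#'   `c("CGS", "W8", "W8_modified", "GC", "CB")`.
#' @param k Word length for the oligomer methods.
#' @param fraction Reference selection fraction for CGS (and the modified
#'   W8 slice).
#' @param fpr Target false-positive rate for the fixed threshold.
#' @param both_strands Count both strands in oligomer frequencies.
#' @return A list per method, each with `scores` (the `score_table`),
#'   `threshold`, `fixed` (the `eval_result` at the fixed-FPR threshold)
#'   and `maximal` (the maximal-discrimination `eval_result`).
#' @export
evaluate_methods <- function(bundle,
                             methods = c("CGS", "W8", "W8_modified", "GC", "CB"),
                             k = 8, fraction = 0.20, fpr = 0.05,
                             both_strands = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  genes <- bundle$seeded
  native_ids <- setdiff(names(genes), bundle$foreign_ids)
  out <- list()
  for (m in methods) {
    scores <- switch(
      m,
      CGS = score_cgs(genes, bundle$core_ids, bundle$test_native_ids,
                      k = k, fraction = fraction,
                      both_strands = both_strands),
      W8 = score_w8(genes, freq_genes = genes, slice_fraction = 1.0, k = k,
                    both_strands = both_strands),
      W8_modified = {
        st <- score_w8(genes, freq_genes = genes[native_ids],
                       slice_fraction = fraction, k = k,
                       both_strands = both_strands)
        st$method <- "W8_modified"
        st
      },
      GC = score_gc(genes),
      CB = score_codon_bias(genes, test_native_ids = bundle$test_native_ids,
                            target_fpr = fpr)
    )
    out[[m]] <- summarize_scores(scores, bundle$foreign_ids,
                                 bundle$test_native_ids, fpr)
  }
  out
}

# Threshold + discrimination summary for one score table.
summarize_scores <- function(scores, foreign_ids, test_native_ids, fpr) {
  final <- stats::setNames(scores$final, scores$gene_id)
  orientation <- score_orientation(scores)
  nat <- final[intersect(test_native_ids, names(final))]
  frn <- final[intersect(foreign_ids, names(final))]
  thr <- threshold_fixed_fpr(nat, fpr = fpr, orientation = orientation)
  list(
    scores = scores,
    threshold = thr,
    fixed = discrimination(frn, nat, thr),
    maximal = maximal_discrimination(frn, nat, orientation = orientation)
  )
}

#' Sweep genome contamination and track each method's discrimination
#'
#' Emulates the reference-poisoning experiment: a fixed probe set of foreign
#' genes (reserved from the tail of the persisted donor order, so it never
#' enters the contamination pool) is scored at each contamination level
#' while `F(p) = round(p N / (1 - p))` additional donor genes from the head
#' of the order are mixed into the genome.  Methods that train on all genes
#' (W8, GC) see their reference drift toward the donor as `p` grows; CGS
#' trains only on the core set, so its scores for the probe and the
#' test-native genes are identical at every level.
#'
#' @param bundle A `benchmark_pair`; its `donor` pool supplies both the
#'   contamination pool and the probe set.
#' @param levels Contamination fractions to test (may include 0).
#' @param probe_size Number of reserved foreign probe genes.
#' @param methods Methods to track (default CGS and W8).
#' @param k,fraction As in [evaluate_methods()].
#' @return A data frame with one row per level and method: `level`,
#'   `method`, `max_discrimination`, plus the number of pool genes used.
#' @export
contamination_sweep <- function(bundle, levels = c(0, 0.05, 0.10, 0.20),
                                probe_size = 40,
                                methods = c("CGS", "W8"),
                                k = 8, fraction = 0.20) {
  donor_order <- with_rng_seed(bundle$seed + 1L, sample(names(bundle$donor)))
  probe_ids <- tail(donor_order, probe_size)
  pool_order <- head(donor_order, length(donor_order) - probe_size)
  target <- bundle$target
  n_native <- length(target)
  probe <- bundle$donor[probe_ids]

  core_ref <- select_reference_oligos(
    aggregate_frequencies(genes_by_id(target, bundle$core_ids), k = k,
                          source = "core"),
    fraction = fraction)

  fixed_profiles <- kmer_profiles(c(target, probe), k)
  rows <- list()
  for (p in levels) {
    f <- n_foreign_for_level(p, n_native)
    if (f > length(pool_order)) {
      stop("donor pool too small for contamination level ", p)
    }
    pool <- bundle$donor[head(pool_order, f)]
    genome <- c(target, pool)
    scored <- c(target, probe)
    for (m in methods) {
      if (m == "CGS") {
        raw <- covariance_scores(scored, core_ref,
                                 profiles = fixed_profiles)
        orientation <- "low"
      } else if (m == "W8") {
        freqs <- aggregate_frequencies(genome, k = k, source = "all")
        ref <- select_reference_oligos(freqs, fraction = 1.0)
        raw <- covariance_scores(scored, ref, profiles = fixed_profiles)
        orientation <- "low"
      } else if (m == "GC") {
        st <- score_gc(scored, genome_gc = gc_fraction(genome))
        raw <- stats::setNames(st$final, st$gene_id)
        orientation <- "high"
      } else {
        stop("unsupported method in contamination_sweep: ", m)
      }
      md <- maximal_discrimination(raw[probe_ids],
                                   raw[bundle$test_native_ids],
                                   orientation = orientation)
      rows[[length(rows) + 1]] <- data.frame(
        level = p, method = m, n_pool = f,
        max_discrimination = md$maximal_discrimination)
    }
  }
  do.call(rbind, rows)
}

#' Sweep the reference frequency slice and track discrimination
#'
#' Re-scores a seeded benchmark with the reference oligonucleotide set
#' restricted to the lowest `slice` fraction of words (plus the pooled
#' remainder), for each requested slice.  Including the most frequent words
#' (`slice = 1`) lets high-frequency repeats shared by donor and target
#' (such as HIP1) dominate the covariance and mask foreign genes.
#'
#' @param bundle A `benchmark_pair`.
#' @param slices Slice fractions, e.g. `seq(0.1, 1, by = 0.1)`.
#' @param reference One of `"core"` (train on core genes, the CGS basis) or
#'   `"all"` (train on all genes of the seeded genome, the W8 basis).
#' @param k Word length.
#' @param zero_override Apply the zero-count override when slicing.
#' @return A data frame with `slice` and `max_discrimination`.
#' @export
slice_sweep <- function(bundle, slices = seq(0.2, 1.0, by = 0.2),
                        reference = c("core", "all"), k = 8,
                        zero_override = TRUE) {
  reference <- match.arg(reference)
  genes <- bundle$seeded
  pool <- if (reference == "core") {
    genes_by_id(bundle$target, bundle$core_ids)
  } else {
    genes
  }
  freqs <- aggregate_frequencies(pool, k = k, source = reference)
  profiles <- kmer_profiles(genes, k)
  rows <- lapply(slices, function(s) {
    ref <- select_reference_oligos(freqs, fraction = s,
                                   zero_override = zero_override)
    raw <- covariance_scores(genes, ref, profiles = profiles)
    md <- maximal_discrimination(raw[bundle$foreign_ids],
                                 raw[bundle$test_native_ids],
                                 orientation = "low")
    data.frame(slice = s, max_discrimination = md$maximal_discrimination)
  })
  do.call(rbind, rows)
}

#' Genome composition statistics
#'
#' @param genome A `DNAStringSet` of replicon sequences.
#' @param genes Optional gene set (for the gene count).
#' @param motif Repeat motif whose density is reported (default HIP1,
#'   `GCGATCGC`).
#' @return A one-row data frame: `genome_id`, `length_nt`, `gc_percent`,
#'   `hip1_per_mb`, `n_genes`.
#' @export
genome_stats <- function(genome, genes = NULL, motif = "GCGATCGC") {
  mc <- S4Vectors::mcols(genome)
  gid <- if (!is.null(mc) && "genome_id" %in% colnames(mc)) {
    as.character(mc$genome_id[1])
  } else {
    "genome"
  }
  gc <- tryCatch(gc_fraction(genome), error = function(e) NA_real_)
  data.frame(
    genome_id = gid,
    length_nt = sum(Biostrings::width(genome)),
    gc_percent = 100 * gc,
    hip1_per_mb = hip1_density(genome, motif = motif),
    n_genes = if (is.null(genes)) NA_integer_ else length(genes)
  )
}
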