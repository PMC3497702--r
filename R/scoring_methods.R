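# Per-gene foreignness scores by the four methods: CGS (core-gene octamer
# similarity), W8 (whole-gene-set octamer covariance, with slice and
# exclude-seeded variants), GC chi-square contrast and codon-usage bias.
#
# The covariance statistic shared by CGS and W8 is, for a gene g,
#
#     raw_g = (1/n) * sum over categories of f_g(category) * f_R(category)
#
# a mean of products without mean-centering, taken over the n categories of
# the reference oligonucleotide set: each member word individually plus (when
# the reference is a strict subset of words) one pooled category for all
# other words combined.  High values mean native-like composition; foreign
# genes fall low.  Final CGS scores are empirical percentiles of raw scores
# among the test-native genes, so they live in [0, 1] and the 5%-quantile
# threshold can be read off directly.

#' Covariance similarity between two category-frequency profiles
#'
#' The elementary statistic behind both the CGS and W8 scores: the mean over
#' categories of the product of the gene-side and reference-side
#' frequencies.
#'
#' @param f_g Numeric vector of category frequencies in the gene.
#' @param f_R Numeric vector of reference category frequencies (same
#'   length/order).
#' @return `mean(f_g * f_R)`.
#' @export
covariance_score <- function(f_g, f_R) {
  stopifnot(length(f_g) == length(f_R))
  mean(f_g * f_R)
}

# Shared scoring engine: raw covariance score of every gene against a
# reference oligonucleotide set.  Gene-side frequencies use the gene's
# countable windows (windows free of ambiguity codes) as denominator; the
# pooled "other" category on the gene side is 1 minus the summed member
# frequencies.  When the reference covers all 4^k words (slice fraction 1)
# no pooled category is used.  Genes with no countable window get NA.
covariance_scores <- function(genes, ref, profiles = NULL) {
  stopifnot(inherits(ref, "ref_oligo_set"))
  nw <- as.integer(4^ref$k)
  include_other <- length(ref$member_idx) < nw
  f_R_full <- numeric(nw)
  f_R_full[ref$member_idx] <- ref$f_R
  member_mask <- logical(nw)
  member_mask[ref$member_idx] <- TRUE
  n_cat <- length(ref$member_idx) + as.integer(include_other)
  if (is.null(profiles)) profiles <- kmer_profiles(genes, ref$k)
  out <- vapply(profiles, function(p) {
    if (p$countable == 0L) return(NA_real_)
    f_g <- p$counts / p$countable
    hit <- member_mask[p$idx]
    s_members <- sum(f_g[hit] * f_R_full[p$idx[hit]])
    if (include_other) {
      f_g_other <- 1 - sum(f_g[hit])
      (s_members + f_g_other * ref$f_R_other) / n_cat
    } else {
      s_members / n_cat
    }
  }, numeric(1))
  names(out) <- names(genes)
  out
}

#' Raw CGS score of a single gene
#'
#' @param gene A `DNAString`, character string, or length-1 `DNAStringSet`.
#' @param ref A `ref_oligo_set` built from the core genes (see
#'   [select_reference_oligos()]).
#' @return The raw covariance score (`NA` if the gene is shorter than `k`).
#' @export
raw_cgs <- function(gene, ref) {
  if (is.character(gene)) gene <- Biostrings::DNAStringSet(gene)
  if (methods::is(gene, "DNAString")) gene <- Biostrings::DNAStringSet(list(gene))
  unname(covariance_scores(gene, ref)[1])
}

#' Empirical percentile of a raw score among test-native raw scores
#'
#' The fraction of test-native genes with raw scores strictly less than the
#' given score.  Vectorized over `raw_score`.
#'
#' @param raw_score Numeric vector of raw scores.
#' @param native_raws Raw scores of the test-native genes (`NA`s dropped).
#' @return Percentiles in `[0, 1]`; low percentiles indicate foreignness.
#' @export
cgs_percentile <- function(raw_score, native_raws) {
  native_raws <- native_raws[!is.na(native_raws)]
  stopifnot(length(native_raws) > 0)
  snat <- sort(native_raws)
  out <- findInterval(raw_score, snat, left.open = TRUE) / length(snat)
  out[is.na(raw_score)] <- NA_real_
  out
}

# Build a score_table data frame.  orientation: side of the scale on which
# foreign genes lie ("low" for covariance scores, "high" for GC and CB).
score_table <- function(method, gene_id, raw, final, orientation) {
  structure(
    data.frame(gene_id = gene_id, method = method, raw = raw, final = final,
               stringsAsFactors = FALSE, row.names = NULL),
    orientation = orientation,
    class = c("score_table", "data.frame")
  )
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table: method=%s, %d genes (%d unscorable), foreign side=%s\n",
              x$method[1], nrow(x), sum(is.na(x$final)),
              attr(x, "orientation")))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Orientation of a score table
#'
#' @param scores A `score_table`.
#' @return `"low"` or `"high"`: the side of the score scale on which
#'   putatively foreign genes lie.
#' @export
score_orientation <- function(scores) attr(scores, "orientation")

#' Score genes by Core Gene Similarity (CGS)
#'
#' Builds the reference oligonucleotide set from the core genes (the least
#' frequent `fraction` of octamers in the core, or all zero-count octamers
#' if more numerous), computes raw covariance scores for every gene, and
#' converts them to percentiles among the test-native genes.  Because the
#' reference derives only from the core set, scores of resident genes are
#' unaffected by foreign genes present elsewhere in the genome.
#'
#' @param genes Named `DNAStringSet` of all genes to score (may include
#'   seeded foreign genes).
#' @param core_ids IDs of the core (training) genes; must be present in
#'   `genes` unless `ref` is supplied.
#' @param test_native_ids IDs of the test-native (calibration) genes.
#' @param k Word length (default octamers).
#' @param fraction Reference selection fraction (default 0.20).
#' @param both_strands Count both strands when building frequencies.
#' @param ref Optionally, a precomputed `ref_oligo_set` (overrides
#'   `core_ids`/`k`/`fraction`).
#' @param two_pass If `TRUE`, core genes themselves are scored by splitting
#'   the core in half and scoring each half against a reference built from
#'   the other half, so that no gene is compared against frequencies it
#'   helped define.  Non-core genes are scored against the full core as
#'   usual.
#' @return A `score_table` with columns `gene_id`, `method`, `raw`, `final`
#'   (CGS percentile in `[0, 1]`); orientation `"low"`.
#' @export
score_cgs <- function(genes, core_ids, test_native_ids, k = 8,
                      fraction = 0.20, both_strands = FALSE, ref = NULL,
                      two_pass = FALSE) {
  if (is.null(ref)) {
    core <- genes_by_id(genes, core_ids)
    ref <- select_reference_oligos(
      aggregate_frequencies(core, k = k, both_strands = both_strands,
                            source = "core"),
      fraction = fraction)
  }
  raw <- covariance_scores(genes, ref)
  if (two_pass && length(core_ids) >= 2) {
    halves <- split(core_ids, rep(1:2, length.out = length(core_ids)))
    for (h in 1:2) {
      other <- halves[[3 - h]]
      ref_h <- select_reference_oligos(
        aggregate_frequencies(genes_by_id(genes, other), k = k,
                              both_strands = both_strands, source = "core"),
        fraction = fraction)
      raw[halves[[h]]] <- covariance_scores(genes_by_id(genes, halves[[h]]),
                                            ref_h)
    }
  }
  native_raws <- raw[intersect(test_native_ids, names(raw))]
  final <- cgs_percentile(raw, native_raws)
  score_table("CGS", names(genes), unname(raw), unname(final),
              orientation = "low")
}

#' Score genes by the W8 whole-gene-set octamer covariance method
#'
#' The same covariance statistic as CGS but with the reference frequencies
#' computed over a pool of genes that, in the standard form, is all
#' protein-coding genes of the (possibly seeded) genome, and with the
#' reference covering all `4^k` words (`slice_fraction = 1`).  Setting
#' `slice_fraction < 1` restricts the reference to the least frequent slice
#' of words plus a pooled category, the frequency-sliced variant.  Passing a
#' native-only pool as `freq_genes` realizes the modified variant in which
#' seeded genes are excluded from the reference frequencies.
#'
#' @param genes Genes to score (named `DNAStringSet`).
#' @param freq_genes Gene pool from which reference frequencies are
#'   computed; defaults to `genes` itself.
#' @param slice_fraction Fraction of lowest-frequency words used as
#'   reference (default 1, i.e. all words).
#' @param k Word length.
#' @param both_strands Count both strands.
#' @param zero_override Apply the all-zero-count-words selection rule when
#'   slicing (see [select_reference_oligos()]).
#' @return A `score_table` with `raw == final`; orientation `"low"`.
#' @export
score_w8 <- function(genes, freq_genes = genes, slice_fraction = 1.0, k = 8,
                     both_strands = FALSE, zero_override = TRUE) {
  freqs <- aggregate_frequencies(freq_genes, k = k,
                                 both_strands = both_strands, source = "all")
  ref <- select_reference_oligos(freqs, fraction = slice_fraction,
                                 zero_override = zero_override)
  raw <- covariance_scores(genes, ref)
  method <- if (identical(slice_fraction, 1.0)) "W8" else "W8_sliced"
  score_table(method, names(genes), unname(raw), unname(raw),
              orientation = "low")
}

#' GC chi-square contrast of a single gene
#'
#' @param obs_gc Observed count of G + C nucleotides in the gene.
#' @param countable_len Number of unambiguous (A/C/G/T) nucleotides.
#' @param genome_gc Genome-wide GC fraction over all protein-coding genes.
#' @return The chi-square statistic
#'   `(obs_GC - exp_GC)^2 / exp_GC + (obs_AT - exp_AT)^2 / exp_AT`; higher
#'   values are more aberrant.
#' @export
gc_chi2 <- function(obs_gc, countable_len, genome_gc) {
  stopifnot(genome_gc > 0, genome_gc < 1)
  if (countable_len == 0) return(NA_real_)
  exp_gc <- genome_gc * countable_len
  exp_at <- countable_len - exp_gc
  obs_at <- countable_len - obs_gc
  (obs_gc - exp_gc)^2 / exp_gc + (obs_at - exp_at)^2 / exp_at
}

#' Score genes by GC contrast
#'
#' Each gene's G + C count is compared by a chi-square statistic to the
#' count expected from the GC fraction over all protein-coding genes (the
#' scored set itself by default, so seeded foreign genes shift the
#' expectation, as in a real contaminated genome).
#'
#' @param genes Genes to score.
#' @param genome_gc GC fraction of the reference pool; computed from
#'   `genes` when `NULL`.
#' @return A `score_table` with `raw == final`; orientation `"high"`.
#' @export
score_gc <- function(genes, genome_gc = NULL) {
  if (is.null(genome_gc)) genome_gc <- gc_fraction(genes)
  af <- Biostrings::alphabetFrequency(genes, baseOnly = TRUE)
  gc <- af[, "C"] + af[, "G"]
  len <- af[, "A"] + af[, "C"] + af[, "G"] + af[, "T"]
  raw <- vapply(seq_along(genes), function(i) {
    gc_chi2(gc[i], len[i], genome_gc)
  }, numeric(1))
  score_table("GC", names(genes), raw, raw, orientation = "high")
}

# ---------------------------------------------------------------------------
# Codon bias

#' Configuration for the codon-bias method
#'
#' The reference gene classes are found by case-insensitive substring search
#' of gene descriptions.  The scale parameter `M` multiplies the
#' predicted-alien decision rule and is normally tuned on the test-native
#' set (see [score_codon_bias()]).
#'
#' @param translation_keywords,chaperone_keywords,ribosomal_keywords
#'   Keyword vectors defining the three highly-expressed reference classes:
#'   translation processing factors, chaperones and ribosomal proteins.
#' @param M Positive scale parameter of the predicted-alien rule.
#' @return An object of class `cb_config`.
#' @export
cb_config <- function(translation_keywords = c("translation", "elongation factor",
                                               "initiation factor"),
                      chaperone_keywords = c("chaperone", "chaperonin",
                                             "heat shock", "groel", "dnak"),
                      ribosomal_keywords = c("ribosomal protein"),
                      M = 1.0) {
  stopifnot(M > 0)
  structure(list(
    reference_class_keywords = list(
      translation = translation_keywords,
      chaperone = chaperone_keywords,
      ribosomal = ribosomal_keywords
    ),
    M = M
  ), class = "cb_config")
}

# Codon counts per gene in reading frame (trailing partial codon dropped,
# with one warning for the whole set).  Returns genes x 64 matrix.
codon_count_matrix <- function(genes) {
  w <- Biostrings::width(genes)
  if (any(w %% 3 != 0)) {
    warning(sum(w %% 3 != 0),
            " gene(s) with length not divisible by 3; trailing partial codon dropped")
    genes <- Biostrings::subseq(genes, 1, w - (w %% 3))
  }
  Biostrings::trinucleotideFrequency(genes, step = 3)
}

# Amino-acid-conditional codon usage from a 64-vector of codon counts.
# Returns list(usage = named numeric over 64 codons normalized within each
# synonymous family, aa_freq = named numeric over amino acids).
codon_usage_profile <- function(codon_counts) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[names(codon_counts)]
  keep <- aa != "*"
  counts <- codon_counts[keep]
  aa <- aa[keep]
  aa_tot <- tapply(counts, aa, sum)
  total <- sum(counts)
  usage <- counts / ifelse(aa_tot[aa] > 0, aa_tot[aa], 1)
  # Families never observed fall back to uniform usage so distances stay
  # defined.
  fam_size <- table(aa)
  zero_fam <- names(aa_tot)[aa_tot == 0]
  usage[aa %in% zero_fam] <- 1 / as.numeric(fam_size[aa[aa %in% zero_fam]])
  list(usage = usage, aa = aa,
       aa_freq = if (total > 0) aa_tot / total else aa_tot)
}

#' Codon-bias distance of a gene to a reference class
#'
#' `B(g|C) = sum_a p_a(g) * sum_{c in codons(a)} |f_g(c|a) - f_C(c|a)|`,
#' where `p_a(g)` is the amino-acid composition of the gene and `f(c|a)` the
#' synonymous codon usage.  Stop codons are excluded.
#'
#' @param gene_counts Named 64-vector of codon counts for the gene.
#' @param class_counts Named 64-vector of pooled codon counts for the
#'   reference class.
#' @return The distance, in `[0, 2]`.
#' @export
codon_bias_distance <- function(gene_counts, class_counts) {
  g <- codon_usage_profile(gene_counts)
  cl <- codon_usage_profile(class_counts)
  d_fam <- tapply(abs(g$usage - cl$usage), g$aa, sum)
  sum(g$aa_freq[names(d_fam)] * d_fam, na.rm = TRUE)
}

#' Resolve the codon-bias reference classes from gene descriptions
#'
#' @param genes Named `DNAStringSet` with `description` metadata.
#' @param config A [cb_config()].
#' @return Named list of gene-ID vectors, one per non-empty class; classes
#'   matching no gene are dropped with a warning.
#' @export
cb_reference_classes <- function(genes, config) {
  desc <- tolower(gene_descriptions(genes))
  classes <- lapply(config$reference_class_keywords, function(keys) {
    hit <- Reduce(`|`, lapply(tolower(keys), function(k) grepl(k, desc, fixed = TRUE)))
    names(genes)[hit]
  })
  empty <- vapply(classes, length, integer(1)) == 0
  if (any(empty)) {
    warning("codon-bias reference class(es) with no matching genes dropped: ",
            paste(names(classes)[empty], collapse = ", "))
  }
  classes[!empty]
}

#' Score genes by codon-usage bias
#'
#' For each gene, codon-bias distances are computed against each
#' highly-expressed reference class (translation factors, chaperones,
#' ribosomal proteins, resolved from gene descriptions) and against the
#' average gene of the genome.  The score is the smallest of those
#' distances: a native gene resembles at least one reference usage, while a
#' foreign gene is distant from all of them.  A gene is called foreign when
#' its score exceeds the scale parameter `M`.  When `test_native_ids` is
#' given, `M` is tuned by monotone bisection so that the target fraction
#' (default 5 percent) of test-native genes is called foreign.
#'
#' @param genes Genes to score.
#' @param config A [cb_config()]; its `M` is used as-is when no tuning set
#'   is supplied.
#' @param test_native_ids Calibration gene IDs for tuning `M` (optional).
#' @param target_fpr Target fraction of test-native genes called foreign.
#' @param class_genes Pool from which reference classes and the average
#'   gene are drawn; defaults to `genes`.
#' @return A `score_table` (orientation `"high"`) with attributes `M`
#'   (tuned scale) and `call` (per-gene `"foreign"`/`"native"`/
#'   `"unscorable"`).
#' @export
score_codon_bias <- function(genes, config = cb_config(),
                             test_native_ids = NULL, target_fpr = 0.05,
                             class_genes = genes) {
  classes <- cb_reference_classes(class_genes, config)
  counts <- codon_count_matrix(genes)
  class_counts_list <- lapply(classes, function(ids) {
    colSums(codon_count_matrix(genes_by_id(class_genes, ids)))
  })
  if (!identical(class_genes, genes)) {
    avg_counts <- colSums(codon_count_matrix(class_genes))
  } else {
    avg_counts <- colSums(counts)
  }
  refs <- c(class_counts_list, list(average = avg_counts))
  n_codons <- rowSums(counts)
  raw <- vapply(seq_along(genes), function(i) {
    if (n_codons[i] < 1) return(NA_real_)
    min(vapply(refs, function(rc) codon_bias_distance(counts[i, ], rc),
               numeric(1)))
  }, numeric(1))
  names(raw) <- names(genes)

  M <- config$M
  if (!is.null(test_native_ids)) {
    nat <- raw[intersect(test_native_ids, names(raw))]
    nat <- nat[!is.na(nat)]
    M <- tune_cb_scale(nat, target_fpr)
  }
  call <- ifelse(is.na(raw), "unscorable",
                 ifelse(raw > M, "foreign", "native"))
  out <- score_table("CB", names(genes), unname(raw), unname(raw),
                     orientation = "high")
  attr(out, "M") <- M
  attr(out, "call") <- unname(call)
  out
}

# Monotone bisection for the predicted-alien scale M: the flagged fraction
# of the calibration scores (score > M) is non-increasing in M, so bisect
# until the largest achievable fraction <= target is reached.
tune_cb_scale <- function(native_scores, target_fpr = 0.05,
                          tol = 1e-9, max_iter = 200) {
  stopifnot(length(native_scores) > 0, target_fpr > 0, target_fpr < 1)
  lo <- 0
  hi <- max(native_scores) + 1
  frac <- function(m) mean(native_scores > m)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (frac(mid) > target_fpr) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  hi
}

#' Z-standardized display scores
#'
#' Standardizes the final scores of a table to mean 0, SD 1 over all scored
#' genes and, for covariance-type methods (orientation `"low"`), reverses
#' the sign so that putatively foreign genes lie on the right of a
#' histogram.  Display only; threshold decisions use raw/final scores.
#'
#' @param scores A `score_table`.
#' @return Named numeric vector of z-scores (`NA` for unscorable genes).
#' @export
zscores <- function(scores) {
  x <- scores$final
  z <- (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
  if (identical(score_orientation(scores), "low")) z <- -z
  names(z) <- scores$gene_id
  z
}

#' Write score tables as TSV
#'
#' Columns `gene_id`, `method`, `raw`, `final`, `z`, `call`.
#'
#' @param scores A `score_table`.
#' @param path Output path.
#' @param threshold Optional `cgs_threshold` used to fill the `call`
#'   column; genes on the foreign side are labeled `"foreign"`.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path, threshold = NULL) {
  tab <- as.data.frame(scores)
  tab$z <- unname(zscores(scores))
  if (!is.null(threshold)) {
    flagged <- flag_foreign(stats::setNames(scores$final, scores$gene_id),
                            threshold)
    tab$call <- ifelse(is.na(scores$final), "unscorable",
                       ifelse(scores$gene_id %in% flagged, "foreign", "native"))
  } else if (!is.null(attr(scores, "call"))) {
    tab$call <- attr(scores, "call")
  } else {
    tab$call <- NA_character_
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
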