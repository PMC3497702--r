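# Threshold selection (fixed false-positive rate, maximal discrimination,
# inflection point), the discrimination statistic, label enrichment and
# score histograms.
#
# All comparisons against a threshold are strict on the foreign side,
# matching the strict "less than" of the CGS percentile: with orientation
# "low" a gene is flagged when score < threshold, with "high" when
# score > threshold.

threshold_obj <- function(value, rule, orientation, target_fpr = NA_real_,
                          achieved_fpr = NA_real_) {
  structure(list(value = value, rule = rule, orientation = orientation,
                 target_fpr = target_fpr, achieved_fpr = achieved_fpr),
            class = "cgs_threshold")
}

#' @export
print.cgs_threshold <- function(x, ...) {
  cat(sprintf("threshold (%s): %.6g, foreign side=%s", x$rule, x$value,
              x$orientation))
  if (!is.na(x$target_fpr)) {
    cat(sprintf(", target FPR=%.3g (achieved %.3g)", x$target_fpr,
                x$achieved_fpr))
  }
  cat("\n")
  invisible(x)
}

#' Gene IDs flagged as foreign by a threshold
#'
#' @param scores Named numeric vector of final scores.
#' @param threshold A `cgs_threshold`.
#' @return Character vector of flagged gene IDs (`NA` scores never flag).
#' @export
flag_foreign <- function(scores, threshold) {
  flagged <- if (threshold$orientation == "low") {
    scores < threshold$value
  } else {
    scores > threshold$value
  }
  names(scores)[which(flagged)]
}

#' Fixed false-positive-rate threshold from test-native scores
#'
#' Finds the score cut that places the largest achievable fraction not
#' exceeding `fpr` of the test-native scores on the foreign side.  The
#' returned value is the midpoint between the bracketing order statistics,
#' so it is robust to floating-point comparison at the boundary.
#'
#' @param native_scores Final scores of the test-native genes.
#' @param fpr Target false-positive rate (default 0.05).
#' @param orientation `"low"` or `"high"`: side on which foreign genes lie.
#' @return A `cgs_threshold` with rule `"fixed_fpr"`.
#' @export
threshold_fixed_fpr <- function(native_scores, fpr = 0.05,
                                orientation = c("low", "high")) {
  orientation <- match.arg(orientation)
  x <- native_scores[!is.na(native_scores)]
  stopifnot(length(x) > 0, fpr > 0, fpr < 1)
  if (length(x) < 1 / fpr) {
    warning(sprintf(
      "only %d native scores: empirical granularity (%.3g) is coarser than the requested FPR (%.3g)",
      length(x), 1 / length(x), fpr))
  }
  u <- sort(unique(x))
  mids <- (head(u, -1) + tail(u, -1)) / 2
  if (orientation == "low") {
    cuts <- c(u[1], mids)
    fracs <- vapply(cuts, function(cut) mean(x < cut), numeric(1))
  } else {
    cuts <- c(mids, u[length(u)])
    fracs <- vapply(cuts, function(cut) mean(x > cut), numeric(1))
  }
  ok <- fracs <= fpr
  best <- which(ok)[which.max(fracs[ok])]
  if (all(fracs[ok] == 0) && length(u) == 1) {
    warning("degenerate score distribution: all native scores equal; nothing flagged")
  }
  threshold_obj(cuts[best], "fixed_fpr", orientation,
                target_fpr = fpr, achieved_fpr = fracs[best])
}

eval_result <- function(frac_foreign, frac_native, threshold,
                        maximal = NA_real_) {
  structure(list(
    frac_foreign_flagged = frac_foreign,
    frac_native_flagged = frac_native,
    discrimination = frac_foreign - frac_native,
    maximal_discrimination = maximal,
    threshold_used = threshold
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "eval_result: foreign flagged %.3f, native flagged %.3f, discrimination %.3f",
    x$frac_foreign_flagged, x$frac_native_flagged, x$discrimination))
  if (!is.na(x$maximal_discrimination)) {
    cat(sprintf(" (maximal %.3f)", x$maximal_discrimination))
  }
  cat("\n")
  invisible(x)
}

#' Discrimination at a fixed threshold
#'
#' Discrimination is the fraction of test-foreign genes flagged minus the
#' fraction of test-native genes flagged at the same threshold, both by
#' strict comparison on the foreign side.
#'
#' @param foreign_scores,native_scores Final scores of the two sets (`NA`s
#'   dropped).
#' @param threshold A `cgs_threshold`.
#' @return An `eval_result`.
#' @export
discrimination <- function(foreign_scores, native_scores, threshold) {
  f <- foreign_scores[!is.na(foreign_scores)]
  n <- native_scores[!is.na(native_scores)]
  stopifnot(length(f) > 0, length(n) > 0)
  if (threshold$orientation == "low") {
    eval_result(mean(f < threshold$value), mean(n < threshold$value),
                threshold)
  } else {
    eval_result(mean(f > threshold$value), mean(n > threshold$value),
                threshold)
  }
}

#' Maximal discrimination over all candidate thresholds
#'
#' Every distinct observed score is tested as a candidate threshold (the
#' returned cut is the midpoint to the next distinct score, for numerical
#' robustness) and the threshold maximizing the discrimination is returned.
#' Ties are broken toward the more conservative threshold, the one flagging
#' fewer native genes.
#'
#' @param foreign_scores,native_scores Final scores of the two sets.
#' @param orientation `"low"` or `"high"`: side on which foreign genes lie.
#' @return An `eval_result` whose `maximal_discrimination` equals its
#'   `discrimination`, with the maximizing threshold in `threshold_used`.
#' @export
maximal_discrimination <- function(foreign_scores, native_scores,
                                   orientation = c("low", "high")) {
  orientation <- match.arg(orientation)
  f <- foreign_scores[!is.na(foreign_scores)]
  n <- native_scores[!is.na(native_scores)]
  stopifnot(length(f) > 0, length(n) > 0)
  u <- sort(unique(c(f, n)))
  mids <- (head(u, -1) + tail(u, -1)) / 2
  if (orientation == "low") {
    cuts <- c(u[1], mids, u[length(u)] + 1)
    disc <- vapply(cuts, function(cut) mean(f < cut) - mean(n < cut),
                   numeric(1))
    # ascending cuts flag more natives as the cut grows; first maximum is
    # the conservative choice
    best <- which.max(disc)
  } else {
    cuts <- c(u[1] - 1, mids, u[length(u)])
    disc <- vapply(cuts, function(cut) mean(f > cut) - mean(n > cut),
                   numeric(1))
    # descending conservativeness: larger cut flags fewer natives
    best <- length(disc) + 1 - which.max(rev(disc))
  }
  thr <- threshold_obj(cuts[best], "max_discrimination", orientation)
  if (orientation == "low") {
    eval_result(mean(f < thr$value), mean(n < thr$value), thr,
                maximal = disc[best])
  } else {
    eval_result(mean(f > thr$value), mean(n > thr$value), thr,
                maximal = disc[best])
  }
}

#' Inflection-point threshold on a sorted score curve
#'
#' The scores are sorted ascending and smoothed by a centered moving average
#' (window truncated at the edges).  The discrete derivative at each point
#' is compared with the derivative averaged over the central fraction of the
#' curve (the flat region); the smoothed value at the lowest-index point
#' whose derivative exceeds that reference is the threshold.  Scores below
#' it (orientation `"low"`) are called foreign.  For score sets smaller than
#' the window, the window shrinks to `max(3, n/10)` points.
#'
#' @param scores Final scores (orientation `"low"`).
#' @param window Moving-average window in points (default 100).
#' @param central Fraction of the curve whose mean derivative is the
#'   reference (default 0.80).
#' @return A `cgs_threshold` with rule `"tr_inflection"`.  If no derivative
#'   exceeds the reference the threshold falls back to the minimum score
#'   (flagging nothing) with a warning.
#' @export
tr_inflection_threshold <- function(scores, window = 100, central = 0.80) {
  x <- sort(scores[!is.na(scores)])
  n <- length(x)
  stopifnot(n >= 3, central > 0, central <= 1)
  w <- if (n >= window) window else max(3, floor(n / 10))
  half <- floor(w / 2)
  cx <- cumsum(c(0, x))
  sm <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    (cx[hi + 1] - cx[lo]) / (hi - lo + 1)
  }, numeric(1))
  # Derivatives are compared only where the smoothing window is complete, so
  # edge truncation cannot masquerade as an inflection.
  valid <- (half + 1):(n - half)
  d <- diff(sm[valid])
  m <- length(d)
  drop_each <- floor(m * (1 - central) / 2)
  central_idx <- (drop_each + 1):(m - drop_each)
  ref <- mean(d[central_idx])
  # Relative tolerance so that an exactly constant-derivative curve (where
  # every point ties the reference up to rounding) falls through to the
  # no-inflection branch.
  tol <- 1e-9 * max(abs(ref), .Machine$double.eps)
  idx <- which(d > ref + tol)
  if (length(idx) == 0) {
    warning("no inflection found (derivative never exceeds the central mean); threshold set below all scores")
    return(threshold_obj(x[1], "tr_inflection", "low"))
  }
  threshold_obj(sm[valid[idx[1]]], "tr_inflection", "low")
}

#' Enrichment of flagged genes in a labeled set
#'
#' Compares the number of flagged genes falling in a labeled set (e.g.
#' genome-island genes or annotated transposases) with the number expected
#' if flags were placed at random, and reports the precision-like ratio
#' observed/total (3 decimals).  Significance of the excess is assessed by a
#' one-sided binomial test.
#'
#' @param flagged_ids Gene IDs flagged as foreign.
#' @param labeled_ids Gene IDs in the labeled set.
#' @param genome_size Total number of genes in the genome.
#' @return A list with `total_flagged`, `observed_in_label`,
#'   `expected_in_label`, `ratio` and `p_value`.
#' @export
label_enrichment <- function(flagged_ids, labeled_ids, genome_size) {
  stopifnot(genome_size >= length(labeled_ids))
  total <- length(flagged_ids)
  obs <- length(intersect(flagged_ids, labeled_ids))
  p0 <- length(labeled_ids) / genome_size
  expected <- total * p0
  if (total == 0) {
    return(list(total_flagged = 0L, observed_in_label = 0L,
                expected_in_label = 0, ratio = NA_real_, p_value = NA_real_))
  }
  list(
    total_flagged = total,
    observed_in_label = obs,
    expected_in_label = expected,
    ratio = round(obs / total, 3),
    p_value = stats::binom.test(obs, total, p0, alternative = "greater")$p.value
  )
}

#' Bin scores for a score-distribution histogram
#'
#' Bins are closed on the left and open on the right.  With `as_z = TRUE`
#' the scores are standardized to mean 0, SD 1 before binning (the standard
#' display uses z units with bins every 0.25).
#'
#' @param scores Numeric scores.
#' @param bin_width Bin width (default 0.25).
#' @param as_z Standardize before binning.
#' @return A data frame with `lower`, `upper` and `count`; counts sum to the
#'   number of scores.
#' @export
score_histogram <- function(scores, bin_width = 0.25, as_z = FALSE) {
  x <- scores[!is.na(scores)]
  stopifnot(bin_width > 0)
  if (as_z) {
    stopifnot(length(x) >= 2)
    s <- stats::sd(x)
    if (s == 0) stop("zero standard deviation; cannot z-transform")
    x <- (x - mean(x)) / s
  }
  lo <- floor(min(x) / bin_width)
  hi <- floor(max(x) / bin_width)
  edges <- (lo:(hi + 1)) * bin_width
  counts <- table(cut(x, breaks = edges, right = FALSE,
                      include.lowest = FALSE))
  data.frame(lower = edges[-length(edges)], upper = edges[-1],
             count = as.integer(counts), row.names = NULL)
}
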