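test_that("fixed-FPR threshold flags the largest achievable fraction <= FPR", {
  set.seed(1)
  x <- sample(seq(0.01, 1, by = 0.01))   # 100 distinct scores
  thr <- threshold_fixed_fpr(x, 0.05, "low")
  expect_equal(sum(x < thr$value), 5)
  s <- sort(x)
  expect_gt(thr$value, s[5])
  expect_lt(thr$value, s[6])
  expect_equal(thr$achieved_fpr, 0.05)

  # high orientation mirrors
  thr_h <- threshold_fixed_fpr(x, 0.05, "high")
  expect_equal(sum(x > thr_h$value), 5)

  # tiny FPR flags nothing (with a granularity warning)
  expect_warning(thr0 <- threshold_fixed_fpr(x, 1e-4, "low"),
                 "granularity")
  expect_equal(sum(x < thr0$value), 0)

  # degenerate all-equal scores flag nothing
  expect_warning(thr_d <- threshold_fixed_fpr(rep(2, 40), 0.05, "low"),
                 "degenerate")
  expect_equal(length(flag_foreign(stats::setNames(rep(2, 40),
                                                   paste0("g", 1:40)),
                                   thr_d)), 0)

  # ties straddling the cut never push the flagged fraction above FPR
  y <- c(rep(1, 6), rep(2, 94))
  thr_t <- threshold_fixed_fpr(y, 0.05, "low")
  expect_equal(mean(y < thr_t$value), 0)
})

test_that("discrimination subtracts flagged fractions at a threshold", {
  thr <- cgshgt:::threshold_obj(2.5, "fixed_fpr", "low")
  r <- discrimination(c(1, 2, 3, 4), c(3, 3.5, 4, 5), thr)
  expect_equal(r$frac_foreign_flagged, 0.5)
  expect_equal(r$frac_native_flagged, 0)
  expect_equal(r$discrimination, 0.5)

  # identical distributions: discrimination 0 at any threshold
  s <- c(1, 2, 3)
  expect_equal(discrimination(s, s, thr)$discrimination, 0)
})

test_that("maximal discrimination matches an enumeration oracle", {
  # perfectly separated
  r <- maximal_discrimination(1:5, 11:15, "low")
  expect_equal(r$maximal_discrimination, 1)
  # same multiset: zero
  set.seed(3)
  s <- runif(40)
  expect_equal(maximal_discrimination(s, s, "low")$maximal_discrimination, 0)
  # interleaved example, enumerable by hand: best achievable is 0
  expect_equal(
    maximal_discrimination(c(2, 4), c(1, 3), "low")$maximal_discrimination,
    0)
  # random score sets against the oracle, both orientations
  for (i in 1:30) {
    f <- round(runif(sample(5:60, 1)), sample(1:3, 1))
    n <- round(runif(sample(5:60, 1)), sample(1:3, 1))
    for (o in c("low", "high")) {
      got <- maximal_discrimination(f, n, o)
      expect_equal(got$maximal_discrimination, oracle_max_disc(f, n, o))
      # the returned threshold reproduces the reported fractions
      chk <- discrimination(f, n, got$threshold_used)
      expect_equal(chk$discrimination, got$maximal_discrimination)
    }
  }
  # never below the fixed-FPR discrimination on the same inputs
  for (i in 1:10) {
    f <- runif(30)
    n <- runif(50)
    thr <- threshold_fixed_fpr(n, 0.05, "low")
    expect_gte(maximal_discrimination(f, n, "low")$maximal_discrimination,
               discrimination(f, n, thr)$discrimination - 1e-12)
  }
})

test_that("tie-breaking picks the conservative maximizing threshold", {
  # two cuts achieve the same discrimination; the conservative one flags
  # fewer natives
  f <- c(1, 2)
  n <- c(10, 11)
  r <- maximal_discrimination(f, n, "low")
  expect_equal(r$maximal_discrimination, 1)
  expect_equal(r$frac_native_flagged, 0)
  expect_lte(r$threshold_used$value, 10)
})

test_that("inflection threshold finds a low tail and falls back on linear ramps", {
  expect_warning(thr <- tr_inflection_threshold(seq(0, 1, length.out = 300)),
                 "no inflection")
  expect_equal(sum(seq(0, 1, length.out = 300) < thr$value), 0)

  set.seed(12)
  scores <- c(rnorm(900, 10, 0.5), rnorm(100, 0, 0.5))
  thr <- tr_inflection_threshold(scores, window = 100, central = 0.80)
  frac <- mean(scores < thr$value)
  expect_gte(frac, 0.05)
  expect_lte(frac, 0.20)

  # small sets shrink the window instead of failing
  set.seed(13)
  small <- c(rnorm(60, 10, 0.5), rnorm(8, 0, 0.5))
  expect_no_error(tr_inflection_threshold(small, window = 100))
})

test_that("label enrichment reports observed/expected and a binomial excess test", {
  flagged <- paste0("g", 1:200)
  labeled <- paste0("g", c(1:30, 500:569))   # 100 labeled, 30 flagged
  r <- label_enrichment(flagged, labeled, genome_size = 1000)
  expect_equal(r$total_flagged, 200L)
  expect_equal(r$observed_in_label, 30L)
  expect_equal(r$expected_in_label, 20)
  expect_equal(r$ratio, 0.15)
  expect_lt(r$p_value, 0.05)

  # labeled = all genes gives ratio 1
  r1 <- label_enrichment(flagged, paste0("g", 1:1000), 1000)
  expect_equal(r1$ratio, 1)

  r0 <- label_enrichment(character(0), labeled, 1000)
  expect_true(is.na(r0$ratio))

  # random flags: the mean ratio over replicates approaches
  # |labeled|/genome_size
  set.seed(21)
  ratios <- replicate(100, {
    label_enrichment(sample(paste0("g", 1:1000), 200), labeled, 1000)$ratio
  })
  expect_lt(abs(mean(ratios) - 0.1), 0.01)
})

test_that("score histograms conserve counts with left-closed bins", {
  h <- score_histogram(c(0.1, 0.1, 0.3), bin_width = 0.25)
  expect_equal(h$count, c(2L, 1L))
  expect_equal(h$lower, c(0, 0.25))

  set.seed(9)
  x <- rnorm(500)
  for (bw in c(0.1, 0.25, 1)) {
    expect_equal(sum(score_histogram(x, bw)$count), length(x))
  }
  hz <- score_histogram(x, 0.25, as_z = TRUE)
  expect_equal(sum(hz$count), length(x))
  expect_error(score_histogram(rep(1, 5), as_z = TRUE), "standard deviation")
})
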