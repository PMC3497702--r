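test_that("overlapping k-mer windows are counted and ambiguity is skipped", {
  r <- count_kmers("ACGTACGTA", 8)
  expect_equal(r$windows, 2L)
  expect_equal(r$counts, c(ACGTACGT = 1L, CGTACGTA = 1L))
  expect_equal(r$skipped, 0L)

  # overlapping occurrences of a palindromic repeat at offsets 0 and 6
  r <- count_kmers("GCGATCGCGATCGC", 8)
  expect_equal(unname(r$counts["GCGATCGC"]), 2L)

  r <- count_kmers("ACGT", 8)
  expect_equal(r$windows, 0L)
  expect_length(r$counts, 0)

  r <- count_kmers("ACGNACGT", 4)
  expect_equal(r$windows, 5L)
  expect_equal(r$skipped, 4L)  # every window touching the N
  expect_equal(sum(r$counts), 1L)
})

test_that("k-mer counter agrees with a character-by-character oracle", {
  set.seed(42)
  for (i in 1:300) {
    k <- sample(1:8, 1)
    s <- random_dna(sample(0:200, 1), p_n = sample(c(0, 0.05), 1))
    got <- count_kmers(s, k)
    want <- naive_count_kmers(s, k)
    expect_equal(sort_named(got$counts), want$counts)
    expect_equal(got$windows, want$windows)
    expect_equal(got$skipped, want$skipped)
  }
})

test_that("frequencies aggregate over effective lengths and normalize", {
  genes <- make_genes(c(g1 = random_dna(15), g2 = random_dna(20)))
  fr <- aggregate_frequencies(genes, k = 8)
  expect_equal(fr$total_effective_length, (15 - 7) + (20 - 7))

  one <- make_genes(c(g = "AAAAAAAA"))
  fr1 <- aggregate_frequencies(one, k = 8)
  expect_equal(unname(fr1$frequencies["AAAAAAAA"]), 1.0)

  # ratio invariance under duplication
  dup <- make_genes(c(a = "ACGTACGTACGT", b = "ACGTACGTACGT"))
  sing <- make_genes(c(a = "ACGTACGTACGT"))
  expect_equal(aggregate_frequencies(dup, 4)$frequencies,
               aggregate_frequencies(sing, 4)$frequencies)

  # normalization: sum of frequencies over all words is 1 when nothing skipped
  set.seed(7)
  genes <- make_genes(stats::setNames(replicate(10, random_dna(150)),
                                      paste0("g", 1:10)))
  for (k in c(2, 4, 6)) {
    expect_equal(sum(aggregate_frequencies(genes, k)$frequencies), 1,
                 tolerance = 1e-12)
  }

  short <- make_genes(c(g = "ACG"))
  expect_error(aggregate_frequencies(short, 8), "no countable windows")
})

test_that("both-strand counting adds reverse-complement counts and doubles length", {
  genes <- make_genes(c(g = "AAAACCCC"))
  fr <- aggregate_frequencies(genes, k = 4, both_strands = TRUE)
  expect_equal(fr$total_effective_length, 2 * 5)
  # reverse complement GGGGTTTT contributes its own windows
  expect_equal(unname(fr$counts["GGGG"]), 1L)
  expect_equal(unname(fr$counts["AAAA"]), 1L)
})

test_that("reference oligo selection takes the lowest-frequency slice", {
  set.seed(11)
  genes <- make_genes(stats::setNames(replicate(20, random_dna(300)),
                                      paste0("g", 1:20)))
  fr <- aggregate_frequencies(genes, k = 4)  # 256 words, ~5860 windows
  ref <- select_reference_oligos(fr, 0.20)
  n_zero <- sum(fr$frequencies == 0)
  expect_equal(length(ref$members),
               if (n_zero > floor(0.2 * 256)) n_zero else floor(0.2 * 256))
  # selection-order property: max member frequency <= min non-member frequency
  non <- fr$frequencies[-ref$member_idx]
  if (length(ref$f_R) > 0 && length(non) > 0) {
    expect_lte(max(ref$f_R), min(non))
  }
  # f_R(other) complements the member mass when nothing was skipped
  expect_equal(ref$f_R_other, 1 - sum(ref$f_R), tolerance = 1e-12)
  expect_equal(ref$n_categories, length(ref$members) + 1L)

  full <- select_reference_oligos(fr, 1.0)
  expect_equal(length(full$members), 256L)
  expect_equal(full$f_R_other, 0)
})

test_that("zero-count words override the fractional cut when more numerous", {
  # 4^4 = 256 words; a tiny gene set leaves most at zero
  genes <- make_genes(c(g = "ACGTACGTACGTACGT"))
  fr <- aggregate_frequencies(genes, k = 4)
  ref <- select_reference_oligos(fr, 0.20)
  expect_true(ref$zero_override_applied)
  expect_equal(sort(ref$member_idx), which(unname(fr$frequencies) == 0))
  expect_true(all(ref$f_R == 0))
})

test_that("GC fraction excludes ambiguity and is strand-symmetric", {
  expect_equal(gc_fraction("GGCC"), 1.0)
  expect_equal(gc_fraction("ATGC"), 0.5)
  expect_equal(gc_fraction("ANNG"), 0.5)
  expect_error(gc_fraction("NNN"), "countable")
  set.seed(3)
  for (i in 1:20) {
    s <- Biostrings::DNAString(random_dna(100))
    expect_equal(gc_fraction(s),
                 gc_fraction(Biostrings::reverseComplement(s)))
  }
})

test_that("repeat density counts overlapping sites per megabase", {
  expect_equal(hip1_density(strrep("A", 10000)), 0)
  # overlapping occurrences count individually
  s <- paste0(strrep("A", 100), "GCGATCGCGATCGC", strrep("A", 100))
  expect_equal(hip1_density(s), 2 * 1e6 / nchar(s))
  # planted sites recovered at least at the planted density
  g <- gen_genome(200000, gc = 0.5, motif = "GCGATCGC",
                  motif_density = 855, seed = 9)
  expect_gte(hip1_density(g), 855)  # 171 planted copies in 0.2 Mb
})

test_that("frequency sets survive a TSV round trip", {
  set.seed(5)
  genes <- make_genes(stats::setNames(replicate(5, random_dna(200)),
                                      paste0("g", 1:5)))
  fr <- aggregate_frequencies(genes, k = 3, source = "core")
  path <- tempfile(fileext = ".tsv")
  export_frequencies(fr, path)
  back <- import_frequencies(path)
  expect_equal(back$k, fr$k)
  expect_equal(back$source, fr$source)
  expect_equal(back$total_effective_length, fr$total_effective_length)
  expect_equal(back$counts, fr$counts)
})
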