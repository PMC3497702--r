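# Synthetic gene sets, genomes and donor pools with controlled GC content,
# genome-specific codon-usage profiles and planted high-frequency repeats,
# so that every scoring and evaluation path can be exercised without
# external data.
#
# Sequences are built from i.i.d. sense codons drawn from a genome-specific
# codon-usage profile.  Codon usage is the dominant source of oligomer
# signature in real coding sequence: preferred and avoided synonymous
# codons differ by an order of magnitude within a genome and the preference
# pattern differs between lineages, which spreads octamer probabilities
# over orders of magnitude and gives the underrepresented-word machinery a
# genuine signature to learn.  Two genomes generated from different profile
# seeds at the same GC emulate evolutionarily distant organisms of similar
# base composition -- the regime where GC contrasts fail but oligomer
# methods can still discriminate.

#' Specification for a synthetic gene set
#'
#' @param n_genes Number of genes.
#' @param gc Target overall GC fraction in `(0, 1)`.
#' @param length_mean,length_sd,length_min Gene length distribution in nt
#'   (normal, clipped below at `length_min`).  Defaults emulate a typical
#'   bacterial length distribution (mean 900 nt, SD 250 nt).
#' @param multiple_of_3 Round lengths to whole codons (default `TRUE`).
#' @param codon_probs Optional named probability vector over the 61 sense
#'   codons.  When `NULL` it is derived from `gc`, `profile_seed` and
#'   `skew` via [genome_codon_probs()].
#' @param profile_seed Seed for the genome-specific codon-usage profile;
#'   `NULL` gives a fixed default profile.  Genomes that should look like
#'   distinct organisms get distinct profile seeds.
#' @param skew Standard deviation of the log-normal codon preference (see
#'   [genome_codon_probs()]).
#' @param planted_motif Optional `list(motif =, density =)`: a k-mer planted
#'   at `density` sites per 1e6 nt (e.g. a HIP1 mimic, `GCGATCGC`).
#' @param genome_id Genome identifier used in gene IDs.
#' @param seed RNG seed; the generated set is a pure function of the spec
#'   including this seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes, gc = 0.5, length_mean = 900,
                           length_sd = 250, length_min = 120,
                           multiple_of_3 = TRUE, codon_probs = NULL,
                           profile_seed = NULL, skew = 0.7,
                           planted_motif = NULL,
                           genome_id = "synth", seed = 1) {
  stopifnot(n_genes >= 1, gc > 0, gc < 1, length_min >= 1,
            length_mean >= length_min, skew >= 0)
  if (!is.null(planted_motif)) {
    stopifnot(is.list(planted_motif),
              all(c("motif", "density") %in% names(planted_motif)),
              planted_motif$density >= 0)
  }
  if (!is.null(codon_probs)) {
    stopifnot(is.numeric(codon_probs), !is.null(names(codon_probs)),
              abs(sum(codon_probs) - 1) < 1e-8)
  }
  structure(list(
    n_genes = as.integer(n_genes), gc = gc, length_mean = length_mean,
    length_sd = length_sd, length_min = length_min,
    multiple_of_3 = multiple_of_3, codon_probs = codon_probs,
    profile_seed = profile_seed, skew = skew,
    planted_motif = planted_motif,
    genome_id = genome_id, seed = seed
  ), class = "synthetic_spec")
}

#' Codon-usage profile for a synthetic genome
#'
#' Builds a probability vector over the 61 sense codons whose expected GC
#' fraction equals `gc`.  Each codon gets a log-normal preference weight
#' `exp(z_c)` with `z_c ~ N(0, skew)` (a fixed default pattern when
#' `profile_seed = NULL`), and the weights are then tilted by
#' `exp(beta * gc(codon))` with `beta` solved so that the expected GC hits
#' the target exactly.  `skew = 0.7` makes preferred and rare codons differ
#' by roughly an order of magnitude, as in real genomes; different profile
#' seeds at the same GC yield genomes with distinct oligomer signatures.
#'
#' @param gc Target GC fraction in `(0, 1)`.
#' @param profile_seed Seed of the preference pattern, or `NULL` for the
#'   default pattern.
#' @param skew SD of the log preference; 0 removes codon bias entirely.
#' @return Named probability vector over the 61 sense codons.
#' @export
genome_codon_probs <- function(gc, profile_seed = NULL, skew = 0.7) {
  stopifnot(gc > 0, gc < 1, skew >= 0)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)[code != "*"]
  z <- if (is.null(profile_seed)) {
    # fixed default pattern (arbitrary but reproducible): alternating signs
    # scaled to the requested skew
    skew * sin(seq(0.5, 30, length.out = length(codons)))
  } else {
    with_rng_seed(profile_seed, stats::rnorm(length(codons), 0, skew))
  }
  gc_codon <- vapply(strsplit(codons, ""), function(b) {
    sum(b %in% c("G", "C")) / 3
  }, numeric(1))
  gc_of_beta <- function(beta) {
    w <- exp(z + beta * gc_codon)
    sum(w * gc_codon) / sum(w)
  }
  beta <- stats::uniroot(function(b) gc_of_beta(b) - gc,
                         lower = -60, upper = 60, tol = 1e-10)$root
  w <- exp(z + beta * gc_codon)
  stats::setNames(w / sum(w), codons)
}

#' Generate a synthetic gene set
#'
#' Draws gene lengths from the spec's length distribution and codons
#' i.i.d. from the spec's codon-usage profile, then plants the requested
#' motif (if any).  Fully determined by the spec, including its seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A named `DNAStringSet` with `genome_id` and `description`
#'   metadata; if a motif was planted, the planted positions are recorded in
#'   the `planted` attribute.
#' @export
gen_gene_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cp <- spec$codon_probs %||%
    genome_codon_probs(spec$gc, spec$profile_seed, spec$skew)
  codons <- names(cp)
  seqs <- with_rng_seed(spec$seed, {
    len <- round(stats::rnorm(spec$n_genes, spec$length_mean, spec$length_sd))
    len <- pmax(len, spec$length_min)
    if (spec$multiple_of_3) len <- 3L * pmax(1L, as.integer(round(len / 3)))
    vapply(len, function(L) {
      n_codon <- ceiling(L / 3)
      s <- paste(sample(codons, n_codon, replace = TRUE, prob = cp),
                 collapse = "")
      substr(s, 1, L)
    }, character(1))
  })
  genes <- Biostrings::DNAStringSet(seqs)
  names(genes) <- sprintf("%s_g%04d", spec$genome_id, seq_len(spec$n_genes))
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    genome_id = rep(spec$genome_id, length(genes)),
    description = rep("hypothetical protein", length(genes))
  )
  if (!is.null(spec$planted_motif) && spec$planted_motif$density > 0) {
    genes <- plant_motif(genes, spec$planted_motif$motif,
                         spec$planted_motif$density,
                         seed = spec$seed + 7919L)
  }
  genes
}

#' Plant a motif into gene sequences at a given density
#'
#' Writes `round(density * total_nt / 1e6)` copies of the motif over the
#' gene set, overwriting sequence in place (lengths are preserved, so
#' effective-length arithmetic is identical between planted and unplanted
#' variants).  Placement is uniform over the non-overlapping motif-length
#' slots tiling each gene, sampled without replacement, which guarantees
#' planted copies never overlap.  Background chance occurrences add to the
#' planted count, so the realized motif density is at least the requested
#' one.
#'
#' @param genes A named `DNAStringSet`.
#' @param motif Motif string (e.g. `"GCGATCGC"`).
#' @param density Target planted density in sites per 1e6 nt.
#' @param seed RNG seed for placement.
#' @return The modified `DNAStringSet`, with a `planted` attribute: a data
#'   frame of `gene_id` and `start` for every planted copy.
#' @export
plant_motif <- function(genes, motif, density, seed = NULL) {
  k <- nchar(motif)
  widths <- Biostrings::width(genes)
  total_nt <- sum(widths)
  n_copies <- as.integer(round_half_up(density * total_nt / 1e6))
  if (n_copies == 0) {
    attr(genes, "planted") <- data.frame(gene_id = character(0),
                                         start = integer(0))
    return(genes)
  }
  slots_per_gene <- widths %/% k
  total_slots <- sum(slots_per_gene)
  if (n_copies > total_slots) {
    stop(sprintf(
      "infeasible density: %d copies requested but only %d non-overlapping slots available",
      n_copies, total_slots))
  }
  chosen <- with_rng_seed(seed, sort(sample.int(total_slots, n_copies)))
  gene_of_slot <- rep(seq_along(genes), slots_per_gene)
  offset <- cumsum(c(0, slots_per_gene))[seq_along(genes)]
  gi <- gene_of_slot[chosen]
  starts <- (chosen - offset[gi] - 1L) * k + 1L
  seqs <- as.character(genes)
  for (j in seq_along(chosen)) {
    substr(seqs[gi[j]], starts[j], starts[j] + k - 1L) <- motif
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(genes)
  S4Vectors::mcols(out) <- S4Vectors::mcols(genes)
  attr(out, "planted") <- data.frame(gene_id = names(genes)[gi],
                                     start = starts,
                                     stringsAsFactors = FALSE)
  out
}

#' Assign highly-expressed reference-class descriptions to random genes
#'
#' Labels random genes as ribosomal proteins, chaperones and translation
#' factors so the codon-bias reference classes resolve on synthetic data.
#'
#' @param genes A named `DNAStringSet`.
#' @param n_each Genes per class.
#' @param seed RNG seed.
#' @return `genes` with updated descriptions.
#' @export
assign_reference_classes <- function(genes, n_each = 8, seed = 1) {
  stopifnot(length(genes) >= 3 * n_each)
  picked <- with_rng_seed(seed, sample(seq_along(genes), 3 * n_each))
  desc <- gene_descriptions(genes)
  desc[picked[seq_len(n_each)]] <-
    sprintf("30S ribosomal protein S%d", seq_len(n_each))
  desc[picked[n_each + seq_len(n_each)]] <-
    rep(c("molecular chaperone DnaK", "chaperonin GroEL"),
        length.out = n_each)
  desc[picked[2 * n_each + seq_len(n_each)]] <-
    rep(c("translation elongation factor Tu",
          "translation initiation factor IF-2"), length.out = n_each)
  mc <- S4Vectors::mcols(genes)
  mc$description <- desc
  S4Vectors::mcols(genes) <- mc
  genes
}

#' Generate a full seeding-experiment bundle
#'
#' Wires the generator to the seeding machinery: generates target and donor
#' gene sets, designates a random core set and the disjoint test-native set,
#' draws the test-foreign set from the persisted donor order, and assembles
#' the seeded genome.  The bundle is fully reproducible from the specs and
#' `seed`.
#'
#' @param target_spec,donor_spec [synthetic_spec()]s for the target genome
#'   and the donor gene pool.
#' @param core_fraction Fraction of target genes designated as core.
#' @param p Contamination fraction of the seeded genome.
#' @param seed Seed for the core/test-native split and the donor order.
#' @param label_classes Assign codon-bias reference-class descriptions to
#'   some core genes (default `TRUE`).
#' @return A list of class `benchmark_pair` with elements `target` (native
#'   genes), `donor` (full donor pool), `core_ids`, `test_native_ids`,
#'   `foreign_ids`, `seeded` (native plus seeded foreign genes), `p` and
#'   `seed`.
#' @export
make_benchmark_pair <- function(target_spec, donor_spec, core_fraction = 0.30,
                                p = 0.03, seed = 1, label_classes = TRUE) {
  target <- gen_gene_set(target_spec)
  donor <- gen_gene_set(donor_spec)
  n_core <- as.integer(round(core_fraction * length(target)))
  stopifnot(n_core >= 20)
  core_ids <- with_rng_seed(seed, sample(names(target), n_core))
  core_ids <- names(target)[names(target) %in% core_ids]  # genome order
  test_native_ids <- exclude_genes(names(target), core_ids)
  if (label_classes) {
    target <- label_core_classes(target, core_ids, seed)
  }
  foreign_ids <- make_test_foreign(donor, p, n_native = length(target),
                                   seed = seed + 1L)
  seeded <- c(target, donor[foreign_ids])
  S4Vectors::mcols(seeded) <- rbind(S4Vectors::mcols(target),
                                    S4Vectors::mcols(donor[foreign_ids]))
  structure(list(
    target = target, donor = donor, core_ids = core_ids,
    test_native_ids = test_native_ids, foreign_ids = foreign_ids,
    seeded = seeded, p = p, seed = seed
  ), class = "benchmark_pair")
}

# Reference-class labels go on core genes: in a real genome the ribosomal/
# chaperone/translation genes are core by definition, and labeling core
# genes keeps the codon-bias training classes out of the test-native set.
label_core_classes <- function(target, core_ids, seed) {
  n_each <- max(3L, min(8L, length(core_ids) %/% 3L))
  core_pos <- match(core_ids, names(target))
  picked <- with_rng_seed(seed + 2L, sample(core_pos, 3 * n_each))
  desc <- gene_descriptions(target)
  desc[picked[seq_len(n_each)]] <-
    sprintf("30S ribosomal protein S%d", seq_len(n_each))
  desc[picked[n_each + seq_len(n_each)]] <-
    rep(c("molecular chaperone DnaK", "chaperonin GroEL"),
        length.out = n_each)
  desc[picked[2 * n_each + seq_len(n_each)]] <-
    rep(c("translation elongation factor Tu",
          "translation initiation factor IF-2"), length.out = n_each)
  mc <- S4Vectors::mcols(target)
  mc$description <- desc
  S4Vectors::mcols(target) <- mc
  target
}

#' @export
print.benchmark_pair <- function(x, ...) {
  cat(sprintf(
    "benchmark_pair: %d target genes (%d core, %d test-native), %d donor genes, %d seeded foreign (p=%.3f)\n",
    length(x$target), length(x$core_ids), length(x$test_native_ids),
    length(x$donor), length(x$foreign_ids), x$p))
  invisible(x)
}

#' Generate a synthetic genome sequence
#'
#' A single contiguous i.i.d. sequence at the given GC, optionally with a
#' planted motif, for genome-level statistics (GC fraction, repeat
#' density).
#'
#' @param length_nt Genome length in nucleotides.
#' @param gc GC fraction.
#' @param motif,motif_density Optional planted motif and its density per
#'   1e6 nt.
#' @param seed RNG seed.
#' @return A `DNAStringSet` of length 1 named `"genome"`.
#' @export
gen_genome <- function(length_nt, gc = 0.5, motif = NULL, motif_density = 0,
                       seed = 1) {
  stopifnot(length_nt >= 1, gc >= 0, gc <= 1)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- with_rng_seed(seed, paste(
    sample(names(probs), length_nt, replace = TRUE, prob = probs),
    collapse = ""))
  g <- Biostrings::DNAStringSet(s)
  names(g) <- "genome"
  if (!is.null(motif) && motif_density > 0) {
    g <- plant_motif(g, motif, motif_density, seed = seed + 7919L)
  }
  g
}
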