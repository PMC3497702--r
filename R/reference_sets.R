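# Construction of the core, test-native and test-foreign gene sets: the
# ortholog-count rule for core genes, the seeding machinery for artificial
# contamination experiments, and deliberate contamination of the core set.

#' Minimum ortholog count for core-gene membership
#'
#' Core genes are those with orthologs in more than a set proportion
#' (default 90 percent) of the maximum ortholog count observed for any gene.
#' The returned value is the cutoff; genes qualify when their count is
#' strictly greater than it.
#'
#' @param max_count Maximum ortholog count over all genes surveyed.
#' @param proportion Proportion of the maximum (in `(0, 1)`).
#' @return `floor(proportion * max_count)`, an integer cutoff.
#' @export
core_threshold <- function(max_count, proportion = 0.90) {
  stopifnot(max_count >= 1, proportion > 0, proportion < 1)
  as.integer(floor(proportion * max_count))
}

#' Read an ortholog-count table
#'
#' Tab-separated `gene_id<TAB>count`, with a header row.  Computing ortholog
#' counts from raw genome comparisons is upstream of this package; the table
#' arrives as a file.
#'
#' @param path Path to the TSV file.
#' @return A named integer vector of ortholog counts.
#' @export
read_ortholog_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "count") %in% colnames(tab))) {
    stop("ortholog table must have columns gene_id and count")
  }
  counts <- as.integer(tab$count)
  names(counts) <- tab$gene_id
  counts
}

#' Select core genes from an ortholog-count table
#'
#' @param counts Named integer vector: ortholog count per gene.
#' @param proportion Proportion of the maximum count a gene must exceed
#'   (strictly) to qualify; see [core_threshold()].
#' @return Character vector of core gene IDs, in table order.
#' @export
select_core_genes <- function(counts, proportion = 0.90) {
  stopifnot(length(counts) > 0)
  cutoff <- core_threshold(max(counts), proportion)
  out <- names(counts)[counts > cutoff]
  if (length(out) == 0) {
    warning("no genes exceed the core-gene ortholog cutoff; ",
            "downstream scoring degrades to an all-gene reference")
  }
  out
}

#' Number of foreign genes needed to contaminate a genome to a given level
#'
#' Solves `F / (F + N) = p` for `F` and rounds half-up, where `N` is the
#' number of native protein-coding genes in the target genome.
#'
#' @param p Contamination fraction of the final seeded genome, in `[0, 1)`.
#' @param n_native Native protein-coding gene count `N`.
#' @return Integer seeded gene count `F`.
#' @export
n_foreign_for_level <- function(p, n_native) {
  stopifnot(p >= 0, p < 1, n_native >= 0)
  as.integer(round_half_up(p * n_native / (1 - p)))
}

#' Draw a reproducible test-foreign gene set from a donor pool
#'
#' All donor genes are placed in a random order which is persisted to
#' `order_file` (when given); experiments at different contamination levels
#' then take their genes from the head of the same fixed order, so a larger
#' experiment always contains the genes of a smaller one and repeated runs
#' return byte-identical sets.  If `order_file` already exists it is reused
#' verbatim and `seed` is ignored.
#'
#' @param donor_genes Named `DNAStringSet` (or character vector of IDs) of
#'   the donor gene pool.
#' @param p Contamination fraction in `[0, 1)`.
#' @param n_native Native gene count `N` of the target genome.
#' @param seed Seed used to create the random order when no order file
#'   exists.
#' @param order_file Optional path at which the order is persisted.
#' @return Character vector of `F = round(p * N / (1 - p))` donor gene IDs.
#' @export
make_test_foreign <- function(donor_genes, p, n_native, seed = NULL,
                              order_file = NULL) {
  ids <- if (is.character(donor_genes)) donor_genes else names(donor_genes)
  f <- n_foreign_for_level(p, n_native)
  if (f > length(ids)) {
    max_p <- length(ids) / (length(ids) + n_native)
    stop(sprintf(
      "donor pool too small: %d genes needed but only %d available (maximum achievable contamination %.3f)",
      f, length(ids), max_p))
  }
  if (!is.null(order_file) && file.exists(order_file)) {
    ord <- readLines(order_file)
    if (!setequal(ord, ids)) {
      stop("persisted order file does not match the donor gene pool: ",
           order_file)
    }
  } else {
    ord <- with_rng_seed(seed, sample(ids))
    if (!is.null(order_file)) writeLines(ord, order_file)
  }
  head(ord, f)
}

#' Deliberately contaminate the core gene set with low-scoring genes
#'
#' Used to test the robustness of the similarity score to foreign genes
#' hiding in its training set: the `m` non-core genes with the lowest raw
#' scores (the genes least like the core) are added so that they make up
#' `level` of the enlarged set, `m = round(level * |core| / (1 - level))`.
#'
#' @param core Character vector of core gene IDs.
#' @param candidate_scores Named numeric vector of raw similarity scores for
#'   candidate genes (scored against the uncontaminated core); core genes
#'   are ignored if present.
#' @param level Target contamination fraction of the enlarged core, in
#'   `[0, 1)`.
#' @return Character vector: core IDs followed by the added contaminants.
#' @export
contaminate_core <- function(core, candidate_scores, level) {
  stopifnot(level >= 0, level < 1)
  if (level == 0) return(core)
  cand <- candidate_scores[!names(candidate_scores) %in% core]
  cand <- cand[!is.na(cand)]
  m <- as.integer(round_half_up(level * length(core) / (1 - level)))
  if (m > length(cand)) {
    stop(sprintf("insufficient candidates: need %d, have %d", m, length(cand)))
  }
  worst <- names(sort(cand))[seq_len(m)]
  c(core, worst)
}

#' Expected percentage of foreign genes among conserved orthologous sets
#'
#' Combines published tree-discordance counts into the expected percentage
#' of genes in orthologous sets that show evidence of horizontal transfer:
#' the fraction of genes that are discordant within the analyzed sets,
#' multiplied by the fraction of all sets that have any conflict with the
#' organismal tree, expressed as a whole percent.
#'
#' @param n_sets Total number of orthologous gene sets surveyed.
#' @param n_no_conflict Number of sets with no conflict against the
#'   consensus organismal tree.
#' @param n_reported_sets Number of conflicted sets with reported tree
#'   analyses (unused by the arithmetic, carried for the record).
#' @param n_genes_in_reported Total genes contained in the reported sets.
#' @param n_discordant_genes Discordant genes found among them.
#' @return Expected foreign percentage, rounded to a whole percent.
#' @export
expected_foreign_fraction <- function(n_sets, n_no_conflict, n_reported_sets,
                                      n_genes_in_reported,
                                      n_discordant_genes) {
  stopifnot(n_sets > 0, n_no_conflict >= 0, n_no_conflict <= n_sets,
            n_genes_in_reported > 0, n_discordant_genes >= 0)
  frac_discordant <- n_discordant_genes / n_genes_in_reported
  frac_conflicted_sets <- (n_sets - n_no_conflict) / n_sets
  round_half_up(frac_discordant * frac_conflicted_sets * 100)
}
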