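# Internal helpers shared across modules.

# Round half away from zero (base round() uses round-half-even).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so package functions never clobber the session stream.
with_rng_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Gene sequences are carried as a Biostrings::DNAStringSet whose names are the
# gene IDs and whose mcols() hold genome_id and description.  This accessor
# subsets by ID with a clear error for unknown IDs.
genes_by_id <- function(genes, ids) {
  missing_ids <- setdiff(ids, names(genes))
  if (length(missing_ids) > 0) {
    stop("unknown gene ID(s): ", paste(missing_ids, collapse = ", "))
  }
  genes[ids]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
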