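# Input/output of gene sets, genomes, ID lists and gene metadata.
#
# Genes are carried as a Biostrings::DNAStringSet on the coding strand, one
# record per protein-coding gene, with names() holding unique gene IDs and
# mcols() holding genome_id and description.  Sequences are never
# reverse-complemented here; both-strand analysis is an option of the
# counting layer.

#' Read protein-coding gene sequences from a multi-FASTA file
#'
#' Each FASTA record is one gene given on the coding strand.  The first
#' whitespace-delimited token of the header is the gene ID; the remainder (if
#' any) is kept as the gene description.  Sequences are uppercased.
#' Characters outside `A`, `C`, `G`, `T`, `N` are either rejected with an
#' error or mapped to `N`, depending on `ambiguous`.
#'
#' @param path Path to a FASTA file of gene nucleotide sequences.
#' @param genome_id Identifier of the genome the genes belong to.
#' @param ambiguous Either `"reject"` (error on IUPAC ambiguity codes other
#'   than `N`) or `"mask"` (replace them with `N`).
#' @return A [Biostrings::DNAStringSet] named by gene ID, with `genome_id`
#'   and `description` metadata columns.
#' @export
read_gene_fasta <- function(path, genome_id, ambiguous = c("reject", "mask")) {
  ambiguous <- match.arg(ambiguous)
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) stop("empty FASTA file: ", path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate gene ID(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  if (any(width(x) == 0)) {
    stop("empty sequence(s) in ", path, ": ",
         paste(ids[width(x) == 0], collapse = ", "))
  }
  names(x) <- ids
  x <- normalize_gene_alphabet(x, ambiguous)
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(
    genome_id = rep(genome_id, length(x)),
    description = desc
  )
  x
}

# Enforce the {A,C,G,T,N} alphabet on a DNAStringSet.
normalize_gene_alphabet <- function(x, ambiguous = c("reject", "mask")) {
  ambiguous <- match.arg(ambiguous)
  af <- Biostrings::alphabetFrequency(x)
  other <- rowSums(af[, !colnames(af) %in% c("A", "C", "G", "T", "N"),
                      drop = FALSE])
  if (any(other > 0)) {
    if (ambiguous == "reject") {
      stop("sequence(s) with characters outside {A,C,G,T,N}: ",
           paste(names(x)[other > 0], collapse = ", "),
           " (use ambiguous = \"mask\" to map them to N)")
    }
    x <- Biostrings::DNAStringSet(
      Biostrings::replaceAmbiguities(x, new = "N")
    )
  }
  x
}

#' Read a genome sequence from FASTA
#'
#' @param path Path to a FASTA file holding one or more replicons.
#' @param genome_id Identifier for the genome.
#' @return A [Biostrings::DNAStringSet] (one element per replicon) with a
#'   `genome_id` metadata column.  Statistics such as GC fraction and repeat
#'   density are computed over exactly the sequences supplied.
#' @export
read_genome_fasta <- function(path, genome_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) stop("empty FASTA file: ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(
    genome_id = rep(genome_id, length(x))
  )
  x
}

#' Write gene records to a FASTA file
#'
#' Headers are `gene_id description` (description omitted when empty), so a
#' round trip through [read_gene_fasta()] restores IDs, sequences and
#' descriptions.
#'
#' @param genes A named [Biostrings::DNAStringSet] of gene sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(genes, path) {
  out <- genes
  desc <- gene_descriptions(genes)
  hdr <- ifelse(nzchar(desc), paste(names(genes), desc), names(genes))
  names(out) <- hdr
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

gene_descriptions <- function(genes) {
  mc <- S4Vectors::mcols(genes)
  if (!is.null(mc) && "description" %in% colnames(mc)) {
    as.character(mc$description)
  } else {
    rep("", length(genes))
  }
}

#' Read a gene-ID list file
#'
#' One ID per line; blank lines and lines starting with `#` are ignored.
#' Every ID must resolve against the loaded gene records; file order is
#' preserved.
#'
#' @param path Path to the ID list.
#' @param genes The loaded genes the IDs must resolve against (a named
#'   `DNAStringSet`), or `NULL` to skip validation.
#' @return A character vector of gene IDs in file order.
#' @export
read_id_list <- function(path, genes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  ids <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(ids) == 0) {
    warning("ID list is empty: ", path)
    return(character(0))
  }
  if (!is.null(genes)) {
    unknown <- setdiff(ids, names(genes))
    if (length(unknown) > 0) {
      stop("unknown gene ID(s) in ", path, ": ",
           paste(unknown, collapse = ", "))
    }
  }
  ids
}

#' Write a gene-ID list file
#'
#' @param ids Character vector of gene IDs.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_id_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' Remove core genes from the test-native set
#'
#' The calibration (test-native) set must not overlap the core training set,
#' otherwise the similarity score is handed an unfair advantage: core genes
#' would be compared against frequencies they themselves defined.
#'
#' @param test_native Character vector of test-native gene IDs.
#' @param core Character vector of core gene IDs.
#' @return `test_native` with all core IDs removed, order preserved.
#' @export
exclude_genes <- function(test_native, core) {
  out <- test_native[!test_native %in% core]
  if (length(out) == 0 && length(test_native) > 0) {
    warning("test-native set is empty after excluding core genes")
  }
  out
}

#' Attach descriptions from a TSV metadata file
#'
#' Expects a tab-separated file with header columns `gene_id` and
#' `description`.  Descriptions drive the keyword search that builds the
#' codon-bias reference classes and any labeled sets (e.g. transposases).
#'
#' @param genes A named `DNAStringSet` of genes.
#' @param path Path to the TSV file.
#' @return `genes` with updated `description` metadata.
#' @export
read_gene_metadata <- function(genes, path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "description") %in% colnames(tab))) {
    stop("metadata file must have columns gene_id and description")
  }
  unknown <- setdiff(tab$gene_id, names(genes))
  if (length(unknown) > 0) {
    stop("unknown gene ID(s) in metadata: ", paste(unknown, collapse = ", "))
  }
  mc <- S4Vectors::mcols(genes)
  if (is.null(mc)) {
    mc <- S4Vectors::DataFrame(genome_id = rep(NA_character_, length(genes)),
                               description = rep("", length(genes)))
  }
  desc <- as.character(mc$description %||% rep("", length(genes)))
  desc[match(tab$gene_id, names(genes))] <- tab$description
  mc$description <- desc
  S4Vectors::mcols(genes) <- mc
  genes
}

#' Extract CDS features from a GenBank flat file
#'
#' A convenience entry point: CDS features are pulled from a GenBank record,
#' using `locus_tag` as the gene ID and `product` as the description.
#' `join(...)` compound locations are concatenated in feature order and
#' `complement(...)` locations are reverse-complemented, so the returned
#' sequence is the coding strand.  FASTA remains the canonical input format;
#' this parser covers the common single-record flat file, not the full
#' GenBank grammar.
#'
#' @param path Path to a GenBank flat file.
#' @param genome_id Genome identifier; defaults to the LOCUS name.
#' @return A named [Biostrings::DNAStringSet] of CDS sequences.
#' @export
read_genbank_cds <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  if (is.null(genome_id)) {
    genome_id <- if (length(locus_line) > 0) {
      strsplit(trimws(sub("^LOCUS", "", locus_line[1])), "\\s+")[[1]][1]
    } else {
      "genbank"
    }
  }
  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0) stop("no ORIGIN section in ", path)
  seq_lines <- lines[(origin_at[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  genome_seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat_at <- grep("^FEATURES", lines)
  if (length(feat_at) == 0) stop("no FEATURES section in ", path)
  feat_lines <- lines[(feat_at[1] + 1):(origin_at[1] - 1)]

  # Split the feature table into individual features (keys start at column 6).
  is_key <- grepl("^     \\S", feat_lines)
  feat_idx <- cumsum(is_key)
  keys <- sub("^\\s*(\\S+).*$", "\\1", feat_lines[is_key])
  cds <- which(keys == "CDS")
  if (length(cds) == 0) stop("no CDS features in ", path)

  records <- lapply(cds, function(i) {
    block <- feat_lines[feat_idx == i]
    # Location may continue over lines until the first qualifier.
    qual_start <- grep("^\\s+/", block)
    loc_end <- if (length(qual_start) > 0) qual_start[1] - 1 else length(block)
    loc <- gsub("\\s", "", paste(
      c(sub("^\\s*CDS\\s+", "", block[1]),
        if (loc_end >= 2) trimws(block[2:loc_end])),
      collapse = ""))
    quals <- paste(trimws(block[-seq_len(loc_end)]), collapse = " ")
    locus_tag <- sub('.*\\/locus_tag="([^"]*)".*', "\\1", quals)
    if (identical(locus_tag, quals)) locus_tag <- NA_character_
    product <- sub('.*\\/product="([^"]*)".*', "\\1", quals)
    if (identical(product, quals)) product <- ""
    list(location = loc, locus_tag = locus_tag, product = product)
  })

  seqs <- vapply(records, function(r) {
    genbank_location_seq(genome_seq, r$location)
  }, character(1))
  ids <- vapply(seq_along(records), function(i) {
    if (is.na(records[[i]]$locus_tag)) sprintf("CDS_%03d", i)
    else records[[i]]$locus_tag
  }, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate locus_tag(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    genome_id = rep(genome_id, length(out)),
    description = vapply(records, `[[`, character(1), "product")
  )
  out
}

# Resolve a GenBank location string (start..end, join(...), complement(...))
# against the genome sequence, returning the coding-strand sequence.
genbank_location_seq <- function(genome_seq, location) {
  loc <- location
  revcomp <- FALSE
  if (startsWith(loc, "complement(")) {
    revcomp <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (startsWith(loc, "join(")) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  parts <- strsplit(loc, ",")[[1]]
  pieces <- vapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    rng <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (length(rng) == 1) rng <- c(rng, rng)
    substr(genome_seq, rng[1], rng[2])
  }, character(1))
  s <- paste(pieces, collapse = "")
  if (revcomp) {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}
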