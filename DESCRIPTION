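Package: cgshgt
Title: Detection of Horizontally Transferred Genes by Core Gene Oligomer
    Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies protein-coding genes of putatively foreign
    (horizontally transferred) origin from anomalous oligonucleotide
    frequencies.  Implements the Core Gene Similarity (CGS) score, which
    trains an octamer reference frequency set on highly conserved core
    genes and restricts it to the most underrepresented words, together
    with three comparator methods (whole-genome octamer covariance W8,
    GC chi-square contrast, and codon-usage bias), empirical-percentile
    and inflection-point threshold rules, seeding-based evaluation of
    discrimination, and a synthetic genome generator with controllable
    GC content, codon-position composition profiles, and planted
    high-frequency palindromic repeats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
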