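Package: teaudit
Title: Reliability Audit of Transposable-Element Subfamily Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing the reproducibility of transposable-element
    (TE) subfamily annotation using biological replicates. Replicate TE pairs
    are extracted from segmental-duplication alignments (or from overlap-paired
    annotation sets), discordant subfamily calls are tabulated, expected
    subfamily drift from point mutations at diagnostic sites is computed from a
    closed-form substitution model, gene-conversion signatures are detected
    with a windowed binomial scan, and ensemble annotation confidence is
    derived from alignment scores via Karlin-Altschul-style lambda inference.
    A synthetic-data generator simulates subfamily libraries with diagnostic
    sites, divergence accumulation, segmental duplication and gene conversion
    with full ground truth, so the whole audit runs end-to-end without genome
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
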