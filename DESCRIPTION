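Package: motifbox
Title: Strictly Valid Single and Structured Motif Extraction from Sequence Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Word-based extraction of strictly valid single and structured
    (multi-box, gapped) motifs from DNA or protein sequence sets. Computes
    fixed-length approximate string matching matrices under the Hamming or
    edit distance model for all ordered sequence pairs, merges per-box
    occurrences under gap-interval constraints with arithmetic-progression
    candidate pruning, and reports motifs meeting a quorum with support and
    weighted support. Includes a planted-motif benchmark generator
    (implantation protocol with exact error budgets and uniform spacers) and
    z-score significance ranking against randomized datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    rlang,
    generics,
    ggplot2,
    readr,
    optparse,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
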