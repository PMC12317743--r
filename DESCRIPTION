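Package: subseedr
Title: Multi-Order Subsequence Seeding for Error-Prone Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Subsequence-based seeding for comparing DNA sequences with high
    error rates. For every length-n window of a sequence the package computes
    the minimal length-k subsequence under each of k jointly defined orders
    (the ABCk orders) by dynamic programming, yielding up to k seeds per
    window in one pass. Includes a reverse-complement-symmetric table
    construction so a window and its reverse complement produce identical
    seed sets, a substring-prefix seed variant, seed matching and evaluation
    metrics (match precision, segment sensitivity, alignment coverage,
    overlap detection), baseline k-mer and minimizer seeders, and simulators
    for edit-distance-binned string pairs, per-position mutation with truth
    alignments, and read sets for overlap experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    jsonlite,
    ggplot2,
    generics,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
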