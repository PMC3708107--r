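Package: rnasnip
Title: Local RNA Secondary Structure Changes Induced by Point Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and scores local changes in the RNA secondary structure
    ensemble caused by single (or few) nucleotide substitutions. Base pair
    probability matrices are computed either with a built-in simplified
    partition-function model (exact McCaskill recursions over a pair-energy
    model, amenable to brute-force verification) or with the ViennaRNA
    programs RNAfold and RNAplfold. Wild-type and mutant ensembles are
    compared with Euclidean distances and Pearson correlations of pairing
    probabilities and their positional profiles, localized to the sequence
    interval of maximal change by an exact interval optimization with a
    self-containedness filter, or approximated by a span-limited scanning
    score for long sequences. Observed scores are converted to empirical
    P values using Gumbel and beta distributions fitted to simulated null
    score distributions on random sequences, and a three-mode pipeline
    (local exact, scanning, and exhaustive screening) reports disrupted
    intervals with their significance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    MASS,
    jsonlite,
    Biostrings,
    IRanges,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
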