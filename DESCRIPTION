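Package: mirhunt
Title: Pre-miRNA Hairpin Classification with ROC-Select Threshold Tuning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification of microRNA precursor (pre-miRNA) hairpins from
    candidate RNA sequences under strong class imbalance. Implements the
    HuntMi approach: sequence- and structure-derived feature extraction for
    candidate hairpins (secondary-structure triplet frequencies, open
    reading frame length, cumulative internal-loop size, low-complexity
    fraction, and a tiered base set of folding features), a built-in
    maximum-pairing secondary-structure backend, negative (pseudo-hairpin)
    training-set construction from genomic sequence with length-distribution
    matching and homology exclusion, and the ROC-select algorithm: pooling
    out-of-fold classifier scores via internal cross-validation, tracing the
    ROC curve, and selecting the decision threshold that maximizes the
    geometric mean of sensitivity and specificity. Includes nested
    grid-based parameter tuning, a stratified cross-validation evaluation
    harness, Friedman/Nemenyi and Wilcoxon comparisons, and seeded synthetic
    data generators for hairpins, pseudo-hairpins and score distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
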