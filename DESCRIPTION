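Package: inosine
Title: Sequence-Based Prediction of A-to-I RNA Editing Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies adenosine-to-inosine (A-to-I) RNA editing sites from
    sequence alone. Fixed-length windows centered on adenosine are encoded by
    nucleotide chemical properties (ring structure, functional group, hydrogen
    bonding) together with the sliding occurrence density of each nucleotide,
    giving a pseudo nucleotide composition (PseKNC) feature vector of four
    channels per position. A support-vector classifier with a radial basis
    kernel is tuned over an exponent lattice of cost and kernel-width
    parameters and evaluated by jackknife, k-fold, and independent-set
    protocols with sensitivity, specificity, accuracy, and the Matthews
    correlation coefficient. Includes benchmark-construction utilities
    (labeling, identity-based redundancy reduction, class balancing), a
    synthetic window generator for end-to-end testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
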