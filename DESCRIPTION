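Package: mirexport
Title: Selective Extracellular Vesicle miRNA Export Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for detecting microRNAs that are selectively exported into
    extracellular vesicles (EVs) from paired cell/EV small-RNA count data, and
    for characterising the RNA sequence signal that drives the sorting.
    Implements low-count filtering, median-of-ratios and RUV-style empirical
    normalisation, negative-binomial Wald tests per compartment, the
    fold-enrichment classifier (log2FC EV minus log2FC cell), de novo ungapped
    RNA motif discovery by zero-or-one-occurrence-per-sequence (ZOOPS)
    expectation-maximisation with an empirical shuffle-calibrated e-value,
    position weight matrix similarity scanning with a percent-of-range score,
    hypergeometric group-specificity enrichment, group comparison of protein
    intensity tables, Hill-equation binding fits, and Poisson-corrected droplet
    digital PCR quantification. A synthetic-data generator reproduces the
    statistical structure of the paired-design experiment so that every stage
    is testable without external data.
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
    jsonlite,
    MASS,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
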