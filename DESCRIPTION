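Package: cvmanova
Title: Cross-Validated MANOVA Decoding of Multichannel Neural Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Time-resolved multivariate decoding of trial-wise neural data by
    cross-validated MANOVA. Estimates noise-normalized pattern distinctness for
    arbitrary contrasts over a factorial condition design, with cross-variable,
    cross-temporal and cross-condition generalization, expected cross-decoding
    under shared representations, searchlight mapping over source
    neighborhoods, single-trial decision-variable readout, signal-detection
    behavioral summaries including maximum-likelihood meta-d-prime, and
    cluster-based sign-permutation group inference. Includes a synthetic-data
    generator that emulates a 32-condition near-threshold detection experiment
    with planted multivariate patterns and known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
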