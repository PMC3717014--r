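Package: refstab
Title: Reference-Gene Stability Validation for RT-qPCR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Validates and ranks candidate reference (housekeeping) genes
    for RT-qPCR normalization. Converts quantification-cycle (Cq) values to
    efficiency-corrected relative quantities, computes geNorm
    expression-stability values (M) and coefficients of variation, performs
    stepwise-elimination stability ranking, and applies the
    pairwise-variation V(n, n+1) criterion to decide how many reference
    genes are needed. Ships a seeded simulator of study-shaped Cq datasets
    with controllable instability for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
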