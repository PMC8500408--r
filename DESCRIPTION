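Package: discriminability
Title: Discriminability Statistics and Permutation Tests for Test-Retest
    Replicability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the test-retest replicability of multivariate
    measurements with the inter-item discriminability statistic (Discr), a
    nonparametric, distance-rank based index of how reliably repeated
    measurements of the same item cluster together. Provides permutation
    tests for whether a dataset is discriminable at all and for whether one
    measurement strategy is more discriminable than another, comparator
    reliability statistics (ICC, PICC, I2C2, fingerprint index, kernel
    k-sample statistic, distance correlation), synthetic benchmark
    generators with a Bayes-accuracy oracle, a power-analysis harness, and
    a strategy-ranking workflow for optimizing experimental design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    sandwich,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
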