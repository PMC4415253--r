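Package: embayesr
Title: Expectation-Maximisation BayesR for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome regression for genomic prediction with a
    four-component normal-mixture (spike-and-normals) prior on SNP effects.
    Implements an expectation-maximisation estimator (emBayesR) whose
    per-marker updates account for the prediction error of all other marker
    effects through a GBLUP-derived prediction-error-variance correction,
    alongside a Gibbs-sampling BayesR reference implementation, GBLUP and
    SNP-BLUP baselines with internal REML variance-component estimation, and
    a quantitative-trait simulator for benchmarking the estimators on
    mixture and single-normal genetic architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
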