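Package: scvqtl
Title: Single-Cell Expression Variance QTL Modelling and Power Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates per-individual, per-gene mean, variance and dispersion
    of latent gene expression from multi-individual single-cell UMI counts by
    maximum likelihood under a zero-inflated negative binomial model with
    technical confounders; provides a randomized-quantile goodness-of-fit
    diagnostic, detection-rate-corrected principal component analysis,
    cis-window QTL scanning with permutation-based gene-level error control,
    empirical-Bayes effect-size deconvolution, and measurement-error-aware
    power and sample-size calculations for eQTL, vQTL and dQTL study design.
    Includes a synthetic-data generator for full QTL studies at realistic
    single-cell scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
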