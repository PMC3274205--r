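Package: ramanid
Title: Raman Spectroscopic Signatures and Discriminant Analysis for Body-Fluid Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for identifying dry traces of blood, saliva and semen from
    near-infrared Raman spectra. Provides spectral preprocessing (despiking,
    grid alignment, normalization, per-sample averaging, difference spectra),
    a synthetic multi-donor multi-spot Raman dataset generator built from
    published band positions of the fluids' chemical components,
    multi-dimensional spectroscopic signature construction (significant factor
    analysis rank estimation, non-negativity-constrained alternating least
    squares, fluorescence baseline terms, SSE/R-squared/RMSE fit reporting),
    and three discriminant engines with chemometric cross-validation: SIMCA
    with Hotelling T-squared and Q statistics, the linear discriminant
    analysis family (LDA, naive Bayes, stratified-covariance, Mahalanobis)
    on PCA or PLS scores, and PLS-DA via SIMPLS.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma
Suggests:
    withr,
    testthat (>= 3.0.0),
    MASS,
    cluster
Config/testthat/edition: 3
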