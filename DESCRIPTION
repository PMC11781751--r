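Package: lbwad
Title: Unsupervised Anomaly Detection and Attribution for Low Birth Weight Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats detection of low (<2500 g), very low (<1500 g) and extreme
    (<1000 g) birth weight as three nested one-class anomaly-detection problems
    on first-trimester tabular cohort data. Provides a preprocessing pipeline
    (weight-threshold stratification, mean/mode imputation, Yes/No and one-hot
    encoding, min-max scaling, normal-only training splits), native reference
    implementations of six anomaly scorers (isolation forest, HBOS, ECOD,
    k-nearest-neighbour distance, Gaussian mixture likelihood, PCA
    reconstruction error) behind a common higher-is-more-anomalous contract
    with an adapter registry for external detectors, a repeated stratified
    cross-validation evaluation protocol with AUCROC/AUCPR and cross-model
    F-tests, two per-instance feature-attribution methods (mean-substitution
    perturbation and local depth-based isolation-forest importance), and a
    synthetic maternal-cohort generator with nested outcome labels for
    end-to-end testing without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
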