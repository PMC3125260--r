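Package: sidefx
Title: Sparse Canonical Correlation Analysis of Chemical Substructures and Drug Side-Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links binary chemical-substructure fingerprints of drugs to their
    recorded side-effect profiles with sparse canonical correlation analysis
    (SCCA), solved as a penalized rank-one matrix decomposition of the
    cross-product matrix with L1 constraints and deflation. Provides ordinary
    CCA under the diagonal-covariance approximation, side-effect profile
    prediction for new molecules from their fingerprints, extraction of
    correlated substructure/side-effect sets, nearest-neighbour, per-label SVM
    and random-assignment baselines, a 5-fold cross-validation harness with
    pooled and per-label ROC/AUC and per-drug top-k accuracy, and a generator
    of synthetic binary profile matrices with planted correlated components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    kernlab,
    MASS,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
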