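Package: potencyUQ
Title: Uncertainty Quantification for Compound Potency Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the relationship between compound potency
    (pIC50) prediction accuracy and prediction uncertainty. Provides a
    synthetic activity-class generator with controlled calibration, numeric
    curation rules for IC50 record tables, uncertainty-aware regression
    models (k-nearest-neighbour and decision-tree ensembles with Tanimoto
    distances, feed-forward networks with Monte Carlo dropout, and
    mean-variance estimation networks trained on Gaussian negative
    log-likelihood), an uncertainty-quantification metric suite (MSE, R2,
    NLL, calibration curves, signed and absolute miscalibration areas,
    Spearman rank correlation between squared error and predicted variance),
    potency-bin-wise confidence analysis, training-set balancing and
    reduction, and an experiment orchestration layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
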