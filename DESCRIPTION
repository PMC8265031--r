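Package: shapknn
Title: Exact Shapley Explanations for k-Nearest-Neighbor Molecular
    Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Game-theoretic explanations for k-nearest-neighbor
    classifiers of the kind used in mass-spectrometry molecular
    diagnostics. Computes exact Shapley values by retraining the
    classifier on every feature subset, four pairwise interaction
    metrics (Shapley interaction indices, Shapley-Taylor interaction
    indices, Harsanyi dividends, and asymmetric Shapley partial sums),
    three SHAP approximations (reference-replacement kernel SHAP,
    multivariate Gaussian conditional SHAP, and Gaussian-copula
    conditional SHAP), and LIME local surrogate explanations with
    logistic-regression and linear-SVM surrogates. A synthetic cohort
    generator emulates correlated log-normal mass-spectral feature
    panels so every computation is reproducible without access to
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    glmnet,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
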