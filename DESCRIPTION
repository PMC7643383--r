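Package: ecgcn
Title: Effective-Connectivity Population-Graph Classification for
    Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Diagnostic pipeline for resting-state fMRI ROI time series:
    group-constrained sparse estimation of directed effective connectivity
    (an l2,1-penalized multi-subject regression solved by a monotone
    proximal-gradient method), Pearson functional connectivity and pairwise
    Granger-causality alternatives, supervised LASSO feature selection,
    construction of a subject population graph combining imaging-feature
    similarity with phenotypic agreement, transductive classification with a
    Chebyshev spectral graph convolutional network, and gradient-based
    sensitivity analysis that maps discriminant features back to directed
    ROI-to-ROI connections. Includes a seeded synthetic-cohort simulator,
    stratified cross-validation, and the classification, McNemar,
    chi-square, t and confidence-interval statistics used to evaluate and
    compare classifiers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    signal,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
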