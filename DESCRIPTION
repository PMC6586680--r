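Package: ensembleSDM
Title: Ensemble Species Distribution Modelling for Climate-Change
    Suitability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for consensus (ensemble) species
    distribution modelling of perennial crops and agroforestry trees under
    climate change. Provides occurrence cleaning and systematic grid
    thinning, pseudo-absence sampling, stepwise variance-inflation-factor
    predictor screening, AUC-weighted consensus suitability modelling with
    k-fold cross-validation and maximum sensitivity-plus-specificity
    binarisation, multi-GCM agreement projection, and downstream change,
    crop-replacement and tree-portfolio analyses. Ships a synthetic
    landscape generator with virtual species of known niche so that every
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    FNN,
    MASS,
    mgcv,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
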