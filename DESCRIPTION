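Package: cytofp
Title: Cytometric Fingerprinting and Machine Learning for Microbial
    Community Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Label-free flow-cytometry fingerprinting of microbial
    communities and its downstream machine-learning analysis. Per-sample
    event clouds (forward scatter, side scatter, autofluorescence) are
    vectorized into fixed-length distribution fingerprints, screened for
    anomalous (perturbed) communities with an autoencoder's reconstruction
    error, and classified into perturbation classes or putative
    anaerobic-digestion functional groups (hydrolyzers, acidogens,
    syntrophic acetogens, methanogens) by gradient boosting, naive Bayes,
    random forests and a three-hidden-layer feed-forward network, compared
    via one-vs-all ROC/AUC with nested cross-validation. Includes an FCS
    3.0/3.1 reader/writer, a class-conditional synthetic event-cloud
    generator for end-to-end testing, and an orchestrated pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    e1071,
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
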