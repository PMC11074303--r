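Package: splitthz
Title: Privacy-Preserving Split Learning for Terahertz Hyperspectral Tissue Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Pixel-wise classification of terahertz-style hyperspectral tissue
    images (fat, muscle, cancer) with a Bayesian ordinal probit head trained
    through an explicit client/server split-learning protocol. Includes a
    labeled synthetic phantom generator with an FFPE-style corruption process,
    spectral preprocessing (Nyquist guard, min-max normalization, FIR low-pass
    filtering), PCA feature extraction, EM-based reliability selection of
    training pixels, MAP and Gibbs inference for the ordinal probit model, a
    transcript-auditing split trainer, and an evaluation battery (pooled
    t-tests on the first principal component, per-region ROC/AUC with Youden
    thresholds, one-vs-rest classification reports, learning curves).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
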