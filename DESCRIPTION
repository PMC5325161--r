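Package: ruleimpute
Title: Missing-Value Imputation and Rule-List Classification for Sparse Clinical Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates clinical-like cohorts with configurable MCAR/MAR/MNAR
    missingness, fills missing cells by mean, distance-weighted k-nearest
    neighbours, missing-aware self-organizing maps, and per-variable C4.5-style
    decision trees, discretizes continuous variables by z-score thresholds,
    weighted-frequency bins, or supervised Bayesian dynamic-programming cuts,
    learns ordered probabilistic rule lists on the discretized data, and
    evaluates imputation-augmented classifiers with cross-validated stability
    and complete-versus-imputed split protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
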