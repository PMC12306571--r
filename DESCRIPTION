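Package: causalrules
Title: Interpretable Heterogeneous Treatment Effect Discovery with Causal Rule Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Discovery and honest inference of heterogeneous treatment effects in
    observational studies by decomposing the conditional average treatment effect
    (CATE) into the average treatment effect plus a sparse linear combination of
    interpretable decision rules. Candidate rules are extracted from a
    gradient-boosted tree ensemble fit to individual treatment effect estimates
    (the fit-the-fit approach), a stable subset is chosen by LASSO-based
    stability selection, and additive average treatment effects (AATEs) for the
    selected rules are estimated on a held-out sample with bootstrap confidence
    intervals. Includes doubly-robust AIPW pseudo-outcomes and S-, T- and
    X-learner meta-estimators behind a pluggable learner interface, and a
    synthetic data generator whose CATE is an exact, known rule decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    xgboost,
    ranger,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
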