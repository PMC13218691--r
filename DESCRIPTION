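Package: gapred
Title: Uncertainty-Aware Genomic Prediction of Athletic Potential
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constrained, uncertainty-aware prediction of a continuous
    athletic-potential score from genotype dosages.  Provides a synthetic
    cohort simulator with linkage-disequilibrium-correlated markers and an
    additive polygenic signal shared across three physical indicators; a
    cohort cleaning, normalization and splitting pipeline; k-nearest-neighbour
    similarity graphs carrying manifold and output-smoothness penalties; a
    three-stage neural predictor (manifold-informed encoder, genomic planner,
    dual-head mean/variance forecaster) trained with a heteroscedastic
    Gaussian negative log-likelihood plus soft constraint terms; Monte-Carlo
    dropout decomposition of predictive variance into aleatoric and epistemic
    parts; and evaluation harnesses for regression metrics, interval
    calibration, prediction-based stratification, uncertainty triage,
    ablation and sensitivity studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
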