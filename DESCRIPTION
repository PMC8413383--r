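Package: scenpred
Title: Scenario-Based Predictive Analytics for Community Health Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A multi-level scenario-based predictive analytics toolkit for
    grouped community-level health outcomes. Provides a library of
    interpretable regression learners (linear models, penalized regression,
    generalized additive models, adaptive regression splines, tree
    ensembles and a Bayesian sum-of-trees sampler) behind one uniform
    fit/predict contract; a repeated randomized 80-20 holdout harness that
    scores models by R-squared, RMSE and MAE against a null baseline and
    selects the best learner; partial dependence plots with 95% bands and
    variable-importance rankings for model interpretation; and a scenario
    engine that fits per-group parametric distributions by the method of
    moments with chi-squared goodness-of-fit family selection, shifts their
    means by +/- 1 standard deviation, resamples with common random
    numbers, and adjudicates directional hypotheses about the projected
    change in the outcome. A synthetic-data generator with known ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    mgcv,
    randomForest,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    optparse,
    withr
Config/testthat/edition: 3
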