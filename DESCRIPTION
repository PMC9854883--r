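Package: fusemble
Title: Classifier Fusion, Ensemble Pruning and Evaluation for Multiclass
    Prediction Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses the per-item class-probability (or hard-label) outputs of
    multiple trained classifiers by soft voting, weighted average voting,
    weighted hard voting, and cross-validated stacking with a gradient-boosted
    or multinomial-logistic meta-learner; optimizes voting weights by
    sequential model-based (Bayesian) search; prunes ensemble membership by
    accuracy ranking over top-k prefixes; and evaluates predictions with a
    one-vs-rest multiclass metric suite (precision, sensitivity, specificity,
    F1, accuracy, macro averages, Wilson and Wald confidence intervals,
    one-vs-rest ROC AUC), McNemar paired-classifier tests, and
    predicted-label correlation diversity diagnostics. Includes a seeded
    generator of correlated multi-classifier prediction sets with calibrated
    per-classifier skill, and count-table fixtures from a published
    four-class liver-ultrasound CNN benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
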