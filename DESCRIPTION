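Package: betaturn
Title: Beta-Turn Prediction with Localized SVMs and Fractional-Polynomial
    Logistic Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts beta-turn residues in protein chains from
    position-specific scoring matrices (PSSMs), predicted secondary
    structure and, optionally, predicted shape strings.  The non-turn
    (majority) class is partitioned into three clusters by k-means, one
    localized radial-basis SVM is trained per cluster-versus-turns subset,
    and the three signed decision values are aggregated by a logistic
    regression whose covariate transforms are chosen from fractional
    polynomials via a deviance-based closed-test procedure.  Ships feature
    encoding, model selection, protein-level cross-validation, evaluation
    metrics (Qtotal, Qpredicted, Qobserved, MCC, ROC/AUC), a seeded
    synthetic-data generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
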