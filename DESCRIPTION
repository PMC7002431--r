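Package: refdnn
Title: Reference-Drug-Based Prediction of Anticancer Drug Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts whether a cancer cell line is resistant or sensitive to a
    drug by representing the drug through its Tanimoto similarities to a panel
    of reference drugs and representing the cell line through the resistance
    probabilities of per-reference-drug sparse logistic (ElasticNet)
    classifiers. The two representations are fused by an element-wise product
    and passed through a small batch-normalized feedforward network. The bank
    of ElasticNet classifiers is trained with the FTRL-Proximal optimizer so
    that l1 regularization yields exact zero coefficients, enabling biomarker
    extraction; the network is trained with Adam on a composite cross-entropy
    loss. Includes k-fold, leave-one-drug-out and leave-one-cancer-type-out
    evaluation protocols, nested cross-validation with Gaussian-process
    Bayesian hyperparameter search, biomarker validation utilities, and a
    synthetic benchmark generator with planted ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
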