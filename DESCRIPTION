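Package: enantiopred
Title: Composite Machine Learning for Reaction Enantioselectivity
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the enantioselectivity (delta-delta-G of activation,
    kcal/mol) of chiral-phosphoric-acid catalysed reactions from numeric
    molecular descriptors grouped by molecule role (solvent, catalyst,
    nucleophile, imine). Provides five base regressors behind one contract,
    Bayesian optimisation of each learner's key hyperparameter,
    Monte-Carlo cross-validation with two-sample z-test comparisons,
    permutation feature importance and partial dependence, and a composite
    model that fits Gaussian mixture densities (EM, BIC component
    selection) over key nucleophile and imine descriptors and routes new
    reaction sets to an overall SVR, a nucleophile-focused random forest,
    or a LASSO model according to average log-likelihood under those
    densities. Includes a generator of structurally realistic synthetic
    reaction tables with controllable distribution shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    rpart,
    randomForest,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
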