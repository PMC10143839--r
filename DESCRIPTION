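Package: dfikit
Title: Drug-Food Interaction Prediction from Chemical Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds multiclass models of drug-food constituent interactions
    directly from SMILES strings. Covers compound ingestion and
    canonicalization, Tanimoto-coefficient structural deduplication,
    rule-based labeling of free-text interaction annotations into negative,
    positive, and non-significant classes, a 3780-dimensional pair
    featurization derived from 60 MOE-type molecular descriptors, a
    four-stage feature-selection cascade (variance threshold, Pearson
    pruning, LASSO, ridge-based recursive feature elimination with
    cross-validation), gradient-boosted multiclass classification with
    additive per-feature attribution, and clinical-style recommendation
    sentences. Cheminformatics primitives are delegated to RDKit through
    the system 'python' interpreter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    nnet,
    ranger,
    stats,
    tibble,
    tools,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with RDKit importable by the
    interpreter on PATH (override via options(dfikit.python = ...))
Config/testthat/edition: 3
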