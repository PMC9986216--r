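Package: denovoSNN
Title: Case/Control Classification and Gene Prioritization from De Novo Coding Variation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies neurodevelopmental-disorder cases against unaffected
    controls from de novo coding variation at very low false-positive rates.
    Builds variant-class-specific (likely gene-disruptive and missense) feature
    matrices augmented with gene constraint and conservation scores (pLI, LOEUF,
    RVIS, phastCons), trains a shallow neural network with a custom loss that
    rewards true positives while penalizing false positives, selects
    hyperparameters by cross-validation on the fraction of cases scored above
    every control, and compares against random-forest, linear-SVM and logistic
    regression baselines, combined (max) and ensemble (mean) predictions, and
    gene-list or constraint-threshold heuristics. Includes a repeated-split
    evaluation harness (TPR at FPR < 0.01, ROC-AUC, PR-AUC, percentile
    confidence intervals, z-scores against a randomized reference model), gene
    ranking through artificial single-variant samples with case/control
    enrichment curves and constraint correlations, and a synthetic cohort
    simulator with planted risk genes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
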