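Package: pathsyn
Title: Pathway-Bridged Prediction of Synergistic Drug Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts cell line-specific synergistic anticancer drug
    combinations from multi-omics data. Drug pairs and cancer cell lines are
    linked through biological pathways: drugs are mapped to pathways via their
    target genes, pathway-pathway Jaccard similarity refines the drug-pathway
    scores, and a symmetric drug-combination-pathway score provides
    interpretable pair features. Cell lines are scored per pathway with a
    single-sample gene-set variation statistic (expression, copy number,
    methylation, RNAi) and mutation-set Jaccard overlap. Dose-response screens
    are summarised into a combination score (mean expected-minus-observed
    growth) and labelled by threshold; gradient-boosted tree classifiers with
    class weighting, undersampling or SMOTE oversampling are trained and
    evaluated with stratified cross-validation, exhaustive feature-set search
    and block-level importance analysis. Includes a combination-versus-best-
    monotherapy viability statistic for wet-lab validation and a synthetic
    data generator with a planted pathway-mediated synergy signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    xgboost,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    pROC,
    glmnet,
    e1071,
    randomForest
Config/testthat/edition: 3
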