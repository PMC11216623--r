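Package: woundrescue
Title: Three-State Rescue Analysis of Wound Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies cell types, genes, expression-trend clusters and
    ligand-receptor signals that shift in non-healing diabetic foot ulcers
    and reverse in healing ulcers, across three clinical states (diabetic
    skin without ulcer, non-healing ulcer, healing ulcer). Provides quality
    control and normalization for labeled single-cell UMI matrices,
    cell-composition log-fold-change rescue classification, per-cell-type
    Wilcoxon differential expression with rescue DEG calling, short
    time-series profile clustering with permutation significance,
    control-binned module scores and preranked gene set enrichment,
    mass-action ligand-receptor communication scoring,
    transcriptional-diversity differentiation scoring, and ROC/AUC
    biomarker screening. Ships a negative-binomial simulator with planted
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
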