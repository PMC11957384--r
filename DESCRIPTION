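Package: psnstrat
Title: Patient Similarity Network Fusion and Graph Convolutional
    Stratification for Longitudinal Multi-Omic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative network stratification of longitudinal multi-omic
    cohorts. Performs per-modality feature selection (negative-binomial
    differential tests, elastic-net regression, variance filtering, principal
    components), builds per-modality patient similarity networks, fuses them
    with similarity network fusion, and classifies participants with a graph
    convolutional network fed by multi-modal two-layer encoders with median
    imputation and mean pooling. Includes a synthetic longitudinal cohort
    generator with per-modality missingness and participant dropout,
    cross-sectional modality-ablation experiments, and longitudinal
    train-at-one-time-point / test-at-others transfer analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
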