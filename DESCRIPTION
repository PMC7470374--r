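Package: surrosig
Title: Surrogate Multigene Assay Risk Scores by Modelling and Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes surrogate versions of three breast-cancer multigene
    assay risk scores (Prosigna risk-of-recurrence, Oncotype DX Recurrence
    Score, MammaPrint gene70 index) from NanoString-style expression panels.
    Two strategies are implemented: "signature-like" scores that apply the
    published algorithms after a single global normalization, and
    "signature-trained" scores calibrated against true assay results on a
    training split (alternating optimization of per-gene centering and
    scaling factors with cross-validated early stopping, metagene-weight
    refitting, and cross-validated ridge classification), then frozen and
    applied to a validation split. A synthetic cohort generator with
    subtype-structured expression, hidden per-gene distortions, tumour
    sizes and vendor-style true scores supports end-to-end evaluation of
    parameter recovery and risk-category concordance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    glmnet,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'panels.R'
    'engines.R'
    'evaluation.R'
    'simulate.R'
    'modelling.R'
    'training.R'
    'io.R'
    'surrosig-package.R'
    'training-mammaprint.R'
    'training-oncotype.R'
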