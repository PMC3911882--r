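Package: ssemtarget
Title: Perturbation Target Ranking with Sparse Simultaneous Equation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts gene targets of external perturbations (drug treatments,
    gene deletions) from expression compendia using sparse simultaneous
    equation models fitted with Lasso regression (SSEM-Lasso). A gene-gene
    interaction matrix is learned row-by-row from an unperturbed training
    compendium; test experiments are then scored by ranking residuals that the
    trained network cannot explain. Includes a synthetic compendium generator
    with known ground truth, gene-set ROC/AUC and rank-percentile evaluation,
    training-compendium modification with rank-change analysis, and an
    end-to-end pipeline for testing-phase and training-phase experiment series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    Matrix,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
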