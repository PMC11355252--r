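Package: octmh
Title: Macular Hole Morphometry and Visual Prognosis from Annotated OCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting 6-month postoperative visual acuity in eyes
    with an idiopathic macular hole from colour-annotated optical coherence
    tomography (OCT) B-scan masks and preoperative clinical records. The
    package extracts handcrafted morphometric features (layer defect lengths,
    shortest inter-component distances, hole diameters, band areas) from
    indexed layer masks, selects explanatory variables by two-group testing
    with iterative variance-inflation-factor elimination, fits an L2-penalised
    logistic prognosis classifier with a precision-favouring decision
    threshold, and evaluates it by repeated stratified k-fold
    cross-validation. A synthetic-data module generates cohort feature tables
    calibrated to published group summary statistics and renders parametric
    macular-hole layer masks with known ground-truth morphometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    Matrix,
    EBImage,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    glmnet
Config/testthat/edition: 3
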