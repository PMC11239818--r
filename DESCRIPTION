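Package: DeltaRadiomics
Title: Longitudinal Multiparametric-MRI Delta Radiomics for Treatment
    Response Prediction
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal radiomic analysis of multiparametric
    breast MRI (DCE early-subtraction and diffusion-weighted volumes)
    aimed at early prediction of pathologic complete response to
    neoadjuvant systemic therapy. Provides histogram-threshold VOI
    refinement, first-order and gray-level co-occurrence matrix (GLCM)
    texture feature extraction, absolute and relative delta features
    across treatment timepoints, univariate AUC screening, elastic-net
    logistic regression with stratified splits and cross-validation,
    support-vector-machine comparators, and inter-/intrareader agreement
    analysis. A fully seeded synthetic cohort generator produces images,
    reader contours and clinical tables with the statistical structure
    the analysis assumes, so the whole pipeline runs end-to-end without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    glmnet,
    pROC,
    e1071,
    RNifti,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
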