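Package: hybridpCR
Title: Hybrid MRI-Radiomics Prediction of Pathologic Complete Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for predicting pathologic complete response
    (pCR) to neoadjuvant chemoradiotherapy in locally advanced cervical
    cancer from T2-weighted MRI and clinical parameters. Implements tumor
    volume preprocessing (resampling, intensity normalisation, tumor-slice
    extraction), a hand-implemented catalogue of shape, first-order and
    gray-level-matrix radiomics features (GLCM, GLRLM, GLSZM, GLDM, NGTDM),
    multi-level globally average-pooled convolutional features from a
    VGG-style backbone, chi-square feature selection, and an
    accuracy-weighted soft-voting ensemble over logistic regression,
    support-vector, k-nearest-neighbour and Gaussian naive Bayes base
    classifiers, evaluated by repeated stratified cross-validation. A
    synthetic phantom-cohort generator makes every stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
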