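Package: muscleCTA
Title: Quantitative Lower-Leg Muscle Radiomics from CT Angiography for
    Peripheral Arterial Disease Severity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to relate quantitative lower-extremity muscle features
    from CT angiography (CTA) to peripheral arterial disease (PAD)
    severity graded by the modified Society for Vascular Surgery runoff
    score.  Provides a synthetic lower-leg CT phantom generator,
    Hounsfield-unit threshold muscle segmentation with structural cleanup
    of bone marrow and veins, a 95-feature histogram and gray-level
    texture bank (GLCM, GLDM, GLRLM, GLSZM, NGTDM) plus shape features,
    z-score standardisation and univariable screening, LASSO-based
    feature selection with logistic regression modelling and ROC/Youden
    evaluation, published fixed-coefficient predictors, and evaluation on
    five equal knee-to-ankle segments of the leg.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    glmnet,
    pROC,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
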