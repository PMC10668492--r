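Package: dualdelta
Title: Dual-Delta Radiomics and Deep Features for Longitudinal CT Nodule Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting histopathological phenotypes (such as spread
    through air spaces, STAS) of lung nodules from paired baseline/follow-up CT
    scans. Implements time-slope delta-radiomics over an IBSI-style 851-feature
    inventory (shape, first-order, GLCM, GLDM, GLRLM, GLSZM, NGTDM and one-level
    3-D wavelet sub-bands) for intratumoral and 3 mm peritumoral regions,
    reproducibility filtering by intraclass correlation, orthogonal-view
    extraction with rigid/affine registration (including a spine-landmark
    fallback), registration-subtracted delta-images, a compact convolutional
    network exposing a 10-neuron-per-view feature layer with Grad-CAM attention
    maps, a 45 x 32 feature-selector/classifier optimization grid scored by
    repeated cross-validated AUC, propensity-score matching, and a synthetic
    longitudinal nodule phantom generator used as the test substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    glmnet,
    pROC,
    e1071,
    ranger,
    MASS,
    rpart,
    nnet,
    class,
    xgboost,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    cluster,
    png,
    withr
Config/testthat/edition: 3
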