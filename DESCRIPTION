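Package: eitwrist
Title: Wrist Kinematics Estimation from Forearm Electrical Impedance Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating multi-degree-of-freedom wrist joint angles
    from forearm electrical impedance tomography (EIT). Implements the
    adjacent-drive/adjacent-measurement stimulation protocol for a 16-electrode
    band, a 2D finite-element forward model with adjoint sensitivity Jacobian,
    one-step Tikhonov-regularized time-difference image reconstruction,
    square-region image features with upper-triangular outer-product
    augmentation, L1-regularized (Lasso) and epsilon-insensitive support vector
    regression of flexion/extension, radial/ulnar deviation and
    pronation/supination angles, session-wise cross-validation with
    RMSE/NRMSE/R-squared reporting, and a synthetic forearm phantom generator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    e1071,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    kernlab,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
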