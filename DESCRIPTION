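Package: elvarkit
Title: Effective Lung Ventilation Area Ratio from Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computer-aided quantitative analysis of chest CT for
    interstitial lung disease. Implements a four-stage ILD-robust lung
    segmentation (coarse air thresholding, Laplacian zero-crossing contour
    detection, mask-hole elimination, contour shrinkage), multi-scale
    Hessian curvature-based lung interstitial enhancement, and the
    Effective Lung Ventilation Area Ratio ELVAR = (L - I)/L from the lung
    voxel count L and the interstitial voxel count I. Includes a digital
    thoracic phantom simulator with paired ground truth, DICOM/NIfTI input
    and output, and cohort-level ROC and Kaplan-Meier stratification of
    ELVAR.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, grDevices, Rcpp, RNifti,
    jsonlite, survival, png
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), pROC, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
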