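Package: perfaid
Title: Automatic Arterial Input Function Estimation and Perfusion Mapping
    for DSC-MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for bolus-tracking (dynamic susceptibility contrast)
    MRI perfusion analysis centred on automatic arterial input function
    (AIF) selection. Provides a multi-stream 3D convolutional network
    that fuses spatial and temporal patch features with a linear-SVM
    late-fusion stage to segment the AIF region, a fuzzy c-means
    comparator, truncated-SVD deconvolution to Tmax/rCBF/CBV/MTT maps,
    perfusion-diffusion mismatch quantification, a synthetic 4D phantom
    generator with ground truth, and evaluation metrics (confusion
    scores, Dice coefficient, AIF curve characteristics, discrete
    Frechet distance).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
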