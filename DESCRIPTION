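Package: aneuscan
Title: Aneurysm Detection in 3D Angiography with a Bayesian-Optimised
    Spherical-Structure Filter
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Automatic detection of intracranial aneurysms in 3D
    angiographic volumes. A Hessian-eigenvalue spherical-structure
    enhancement filter is tuned per target by Gaussian-process Bayesian
    optimization of its scale and cutoff parameters; detections are
    extracted by adaptive thresholding on the mean or maximum filter
    response of a 26-connected region grown from the response peak, and
    multiple aneurysms are found by iterative removal. Includes volume
    input/output for NIfTI, MetaImage and TIFF stacks, a synthetic
    vascular phantom generator with ground truth, and detection
    evaluation via precision-recall and ROC analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    lhs,
    png,
    Rcpp,
    RNifti,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    oro.nifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
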