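Package: prm3d
Title: Parametric Response Mapping and 3D-CNN Classification of Paired Lung CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise parametric response mapping (PRM) of registered
    inspiration/expiration thoracic CT into normal, functional small-airway
    disease (fSAD) and emphysema classes, registration-derived functional
    variables (Jacobian determinant, anisotropic deformation index, slab-rod
    index, air-volume change), a nine-layer volumetric convolutional network
    for COPD versus non-COPD classification with five-fold cross-validation,
    and volumetric Grad-CAM saliency maps. Includes a synthetic paired-CT
    phantom generator with planted disease burdens and ground-truth
    displacement fields so the whole pipeline is testable without clinical
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    yaml,
    png,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
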