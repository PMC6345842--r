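Package: radrobust
Title: Robustness of Radiomic Features by Image Perturbation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses the robustness of radiomic image features from single
    images, as an alternative to test-retest imaging. A 3D CT image and a
    region-of-interest mask are perturbed by chains of rotation, Gaussian
    noise addition, sub-voxel translation, mask volume adaptation and
    supervoxel-based contour randomisation. Features from eleven IBSI-style
    families (morphology, local intensity, intensity statistics, intensity
    histogram, intensity-volume histogram and six texture-matrix families)
    are computed at several isotropic voxel spacings and discretisation
    settings, and per-feature robustness is classified from the 95 percent
    confidence interval of the intraclass correlation coefficient ICC(1,1)
    against a threshold of 0.90. Includes a synthetic phantom generator so
    the whole workflow can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
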