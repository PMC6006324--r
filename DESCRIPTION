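Package: jsmap
Title: Joint Space Mapping from Clinical CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Three-dimensional, sub-voxel measurement of joint space width from
    clinical CT volumes. Builds a triangulated joint space patch on the femoral
    bone surface, samples interpolated line profiles along vertex normals, fits a
    Gaussian-blurred double-peak cortical density model with a fixed peak density
    constraint, and deconvolves to locate the opposing outer bone surfaces at
    sub-voxel precision. Also provides the high-resolution adaptive half-maximum
    reference measurement, mutual-information volume registration, similarity plus
    thin-plate-spline surface registration onto an average surface, agreement and
    reproducibility statistics (Bland-Altman limits, RMSCV), and a synthetic
    phantom generator with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    minpack.lm,
    igraph,
    jsonlite,
    tibble,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
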