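Package: vasculometry
Title: Layer-Resolved Cerebrovascular Morphometry and Reactivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of cortical microvasculature from
    volumetric optical imaging. Converts Doppler phase volumes to blood-flow
    velocity (mm/s), aligns the cortical surface, segments vessels in 3D with
    a multiscale Hessian (Frangi) vesselness filter, skeletonizes them by 3D
    parallel thinning, and extracts a vessel graph for layer-wise morphometry
    (vessel density, skeleton density, bifurcation index, tortuosity).
    Computes laser-speckle cerebrovascular-reactivity metrics (time to
    plateau, peak response, integrated reactivity) and scores each vascular
    parameter's two-group classification accuracy with a bootstrap plus
    leave-one-out cross-validated RBF support vector machine. Includes a
    synthetic phantom generator with exact ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
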