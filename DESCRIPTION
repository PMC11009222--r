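Package: retialign
Title: Wide-Field to Ultra-Wide-Field Retinal Image Registration with
    Spherical-Eye Distortion Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Deterministic feature-based registration of steered wide-field
    (WF) fundus images to a single ultra-wide-field (UWF) reference image.
    Implements soft-Dice vessel-map overlap scoring, second-order polynomial
    warping estimated by weighted least squares, bidirectional-consensus
    descriptor matching, RANSAC with consensus-set refinement and a
    deterministic IRLS robust-reweighting alternative, a five-parameter
    spherical-eye camera model with stereographic UWF projection for
    iterative 3D distortion correction, Gaussian-feathered composite
    generation, and a phantom-eye simulator that provides ground-truth
    poses and correspondences for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
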