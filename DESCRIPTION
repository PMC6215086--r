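Package: serialoct
Title: Dual-Resolution Serial Blockface OCT Reconstruction and OCT-dMRI Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational pipeline for dual-resolution serial blockface
    optical coherence tomography (OCT) of whole mouse brains: swept-source
    fringe reconstruction with Gaussian apodization, attenuation-coefficient
    estimation and depth compensation, stage-model calibration and tile
    mosaicking with diffusion-style blending, 3-D whole-brain assembly,
    Fibonacci autofocus, water/tissue interface detection with Zernike
    characterization of the focal surface, probability-guided automated
    region-of-interest selection, multiresolution ROI mapping through affine
    transforms, ex vivo diffusion MRI signal-drift compensation anchored on
    cerebrospinal fluid, and quantile-grouped multimodal OCT/dMRI feature
    comparison. A seeded digital phantom and fringe/DWI simulator replaces the
    scanner hardware so that every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
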