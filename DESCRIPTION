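Package: dirqc
Title: Quality Control for Deformable Image Registration with CBCT Noise Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for validating deformable image registration (DIR) in
    radiotherapy workflows. Measures the noise power spectrum (NPS) of CT and
    cone-beam CT (CBCT) images from uniform-phantom scans, fits a parametric
    ramp-up/roll-off spectral model, and synthesizes noise fields matched in
    magnitude and texture so planning CTs can be turned into pseudo-CBCTs.
    Quantifies registration accuracy against ground truth via landmark
    propagation error and deformation-vector-field differences with
    contour-masked statistics, and provides the computational core of
    user-guided local refinement: box-based translation alignment by
    sum-of-squared-differences minimization and vector locking. Reads and
    writes MetaImage, NIfTI and DICOM series volumes, displacement fields and
    landmark lists, and ships a command-line interface plus seed-deterministic
    synthetic fixtures for every component.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    RNifti,
    tibble,
    ggplot2,
    rlang,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
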