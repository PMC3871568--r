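Package: murinod
Title: Semi-Automated Murine Lung Nodule Volumetry and Growth Kinetics from Micro-CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring mouse lung tumors in micro-CT volumes.
    Implements a semi-automated nodule segmentation pipeline (seed stroke,
    cubic region of interest, adaptive bimodal-histogram threshold,
    morphological vessel removal, juxtapleural chest-wall separation),
    volumetric measurement methods (voxel counting, cylindrical
    bi-dimensional approximation, planimetric contours), exponential
    growth-kinetics analysis (volume doubling time, growth index, slope
    comparison), and a synthetic thorax-phantom generator with analytic
    ground truth for end-to-end validation.  Reads calibrated Hounsfield-unit
    volumes from DICOM series or NIfTI files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
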