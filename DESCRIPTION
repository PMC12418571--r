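Package: vvoqc
Title: Voxel-Size-Sensitive Motion Quality Control for fMRI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes voxel volume overlap (VVO) motion indicators from
    rigid-body realignment parameters. The exact volumetric overlap between a
    reference voxel cuboid and its rigidly moved copy is obtained by iterative
    half-space clipping, yielding per-timepoint total-displacement and
    scan-to-scan overlap percentages (TD_VVO, STS_VVO) at six representative
    cortical-distance locations, an out-of-plane motion decomposition by
    acquisition plane, voxel-size sweep simulations, a constrained linear
    calibration against conventional scan-to-scan displacement, quality
    classification, and censoring regressors for GLM analyses. Reads SPM,
    FSL and BIDS motion-parameter dialects and NIfTI headers; writes JSON and
    CSV quality-control reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    readr,
    jsonlite,
    RNifti,
    ggplot2,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
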