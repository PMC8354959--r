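Package: erasevae
Title: Unsupervised Anomaly Segmentation in Brain MRI with Spatially Erased
    Variational Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised anomaly segmentation for volumetric brain MRI using
    2D and 3D variational autoencoders trained only on healthy scans.
    Implements structured spatial input erasing (single cube/patch,
    multi-cube, half-volume/half-slice; zero or sampled-noise fill) as an
    in-painting regularizer, residual-map segmentation with eroded-mask and
    median-filter post-processing, greedy bisection calibration of the
    binarization threshold, and voxel-wise plus slice-wise evaluation (Dice,
    area under the precision-recall curve). Ships a synthetic brain-phantom
    generator with lesion insertion and ground-truth masks so the full
    pipeline runs end-to-end without external data, and a NIfTI
    preprocessing chain (isotropic resampling, robust intensity
    normalization, crop/pad, downsampling to the canonical training grid).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    readr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
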