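Package: pointsr
Title: Super-Resolution and Denoising of Point-Scanning Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for deep-learning super-resolution and denoising of
    point-scanning microscopy images (confocal, scanning electron). Training
    pairs are generated semi-synthetically at runtime by "crappification":
    high-resolution images are downsampled and then corrupted with
    value-dependent noise, so that only high-quality acquisitions are needed
    for training. Crappifier noise parameters can be calibrated against real
    high/low-resolution pairs via noise-profile extraction and Gaussian-process
    Bayesian optimization. Includes leakage-safe tiled datasets for
    n-dimensional images, a residual U-Net restoration model with a
    self-contained CPU training engine (multi-scale SSIM + L1 loss), tiled
    whole-image prediction, benchmarking against a bilinear-upscaling control,
    a synthetic specimen generator for end-to-end testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tiff,
    Rcpp,
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    lhs
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
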