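Package: intensify3d
Title: Signal Intensity Normalization for Large Fluorescence Microscopy Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: User-guided normalization of signal intensity within and across
    large single-channel fluorescence microscopy image stacks (2-photon,
    light-sheet). Implements the Intensify3D procedure: per-plane background
    estimation by signal removal and Savitzky-Golay smoothing, correction by
    division, and cross-stack harmonization via upper-quantile, contrast-stretch
    or semi-quantile normalization of 10,000 recorded quantiles. Includes
    automatic tissue detection (PCA features with Gaussian-mixture or k-means
    clustering), a Gaussian-sphere phantom generator with four analytic
    distortion fields for validation, and a threshold-based 3D object-counting
    evaluator for scoring restoration quality against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0),
    mclust
Imports:
    tiff,
    signal,
    igraph,
    EBImage,
    withr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
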