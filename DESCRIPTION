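Package: pufkit
Title: Image-Based Physically Unclonable Functions from Fractal Self-Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for optical physically unclonable functions
    (PUFs) whose entropy source is a fractal self-assembly image. Grows
    diffusion-limited aggregation (DLA) clusters as a synthetic stand-in for
    micrographs of protein dendrites, binarizes them (Otsu, global or adaptive
    thresholding), stamps corner fiducial markers, digitizes each image into a
    fixed-length cryptographic key through a decapitated convolutional feature
    extractor with mean-threshold quantization, Von Neumann debiasing and a
    standard-size key derivation step, scores key quality with bit uniformity,
    pairwise inter-device Hamming distance and six NIST SP 800-22 statistical
    tests, and authenticates degraded phone-style captures against the
    enrolled device library via fiducial registration and bitwise matching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    dplyr,
    ggplot2,
    grDevices,
    graphics,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
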