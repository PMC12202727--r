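Package: voidlapse
Title: Simulation, Reconstruction and Quantification for Single-Cell
    Time-Lapse MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for time-lapse MRI of single iron-labeled
    cells and micron-sized iron particles. Provides an analytic rotating
    digital phantom with point-like signal voids, 2D Cartesian and
    interleaved 3D radial balanced-SSFP acquisition simulation with complex
    Gaussian noise, density-compensated Kaiser-Bessel gridding and
    compressed-sensing reconstruction with temporal total variation,
    retrospective fully-sampled/undersampled framing, dual-half-echo
    combination, zero-filling contrast enhancement, and the downstream
    quantification stack: signal loss, void size, SNR, CNR with Rayleigh
    correction, nearest-neighbour spot tracking, and estimation of the
    velocity detection limit by dual-regression intersection with error
    propagation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    RNifti,
    tiff,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
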