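Package: mobir
Title: Modulation-Based X-Ray Phase-Contrast and Dark-Field Imaging
Version: 0.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and retrieval toolkit for single-mask (modulation-based)
    X-ray phase-contrast and dark-field imaging. Generates structured-illumination
    membranes of four topologies (random, hexagonal, square, Vogel spiral),
    simulates reference/sample detector image pairs for parametric nylon phantoms
    in a cone-beam geometry, retrieves absorption, refraction displacement,
    scalar and directional (tensor) dark-field via an implicit per-pixel
    least-squares system built on transport-of-intensity and optical-flow
    conservation, and scores the retrieved displacement images with standard
    image-quality metrics (NRMSE, SSIM family, Fourier ring correlation) plus
    angular-sensitivity and mask-diagnostic analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
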