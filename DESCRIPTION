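Package: echosynth
Title: Physics-Guided Speckle Synthesis and Mask-Conditioned GANs for
    Ultrasound Phantom Images
Version: 0.1.0
Authors@R:
    person("echosynth", "developers", email = "echosynth@example.org",
           role = c("aut", "cre"))
Description: Simulates fully developed ultrasound speckle by Fourier-optics
    spectral filtering with a learnable square aperture, warps speckle
    between polar and Cartesian grids for centric (catheter-based) views,
    and assembles a mask-conditioned generative adversarial network with
    spatially-adaptive normalization, spectral normalization and a
    multi-size speckle bank with channel attention.  Ships a synthetic
    artery mask/phantom generator for intravascular ultrasound style
    images, an evaluation suite (Frechet distance on embedded features,
    per-class gray-value Jensen-Shannon divergence, SSIM, Dice, modified
    Hausdorff distance) and a command-line interface.  All training and
    evaluation runs on synthetic phantoms; no external dataset is needed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
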