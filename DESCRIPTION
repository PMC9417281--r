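Package: nanoshape
Title: Soft Shape Classification and Metrology of Nanoparticles from
    Electron Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised shape metrology for convex nanoparticles imaged by
    transmission electron microscopy. Extracts closed particle contours from
    calibrated micrographs (Fourier/Gaussian denoising, intensity thresholding,
    boundary tracing), computes size- and orientation-invariant log-Hu moment
    shape descriptors with an inertia-eigenvalue parameterization, and performs
    soft (probabilistic) shape classification by expectation-maximization of a
    Gaussian mixture model with automatic class-count reduction. Touching and
    aggregated particles are separated by a sign-of-curvature
    difference-of-Gaussians binarization followed by FFT-accelerated affine
    fitting of averaged shape templates. Includes a synthetic micrograph
    generator for validation, responsibility-weighted diagnostics
    (contour-density maps, eigenvalue scatter, effective-diameter
    distributions), and a batch pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
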