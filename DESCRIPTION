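Package: modcor
Title: Modular Correlation Networks in Developing Cortical Spontaneous Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of large-scale modular spontaneous activity in widefield
    and two-photon calcium imaging of developing visual cortex. Provides
    baseline (rank-order filter) correction and Delta-F/F computation, detection
    of spatially extended spontaneous events, seed-point Pearson correlation
    networks with rotation/translation/reflection surrogate null models,
    correlation fractures, modular wavelength and local eccentricity of
    correlation patterns, active-domain size via rotated two-dimensional
    Gaussian fits, participation-ratio dimensionality, second-order similarity
    between excitatory and inhibitory networks, and cellular-resolution
    correlation analyses. Includes a synthetic-data generator with known ground
    truth (low-rank modular pattern basis, paired dual-indicator movies, cell
    populations with neuropil contamination) for validating every stage of the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    signal,
    minpack.lm,
    jsonlite,
    tiff,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
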