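Package: spectralTIE
Title: Single-Shot Quantitative Phase Imaging by Spectral Multiplexing of Defocus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and inverse solver for single-shot quantitative
    phase imaging (QPI) with a chromatically dispersive hyperboloid metalens.
    The longitudinal chromatic aberration of a diffractive lens maps the red,
    green and blue channels of a color sensor onto distinct defocus planes, so
    one RGB exposure carries a through-focus measurement. The package provides
    scalar Fresnel propagation and digital refocusing, synthetic pure-phase
    targets (Siemens star, precision diffuser screen, filament phantoms), a
    sensor chain with Bayer mosaic, photon/read noise and intensity-only
    coherent fiber-bundle transmission, and a spectral transport-of-intensity
    solver: regularized double FFT-Poisson inversion with iterative residual
    refinement, phase-to-height conversion, channel-defocus calibration, and
    validation metrics (contrast transfer curve, phase RMSE, optical budget).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
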