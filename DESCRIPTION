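Package: ramanreactor
Title: Label-Free Raman Monitoring of Metabolic Gradients in a
    Diffusion-Limited Microreactor
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and chemometric analysis of spatially resolved Raman
    spectra from a diffusion-limited cell-culture microreactor. Provides a
    reaction-diffusion forward model of nutrient, lactate, pH and
    stress-metabolite gradients along a 15 mm chamber; a spectral renderer
    with Lorentzian/Gaussian band models, pH-dependent buffer bands, glass
    window signatures, detector noise and cosmic-ray spikes; the standard
    Raman preprocessing chain (despiking, Savitzky-Golay smoothing,
    asymmetric-least-squares baseline correction, mean centering, replicate
    averaging); PCA, ANOVA-simultaneous component analysis (ASCA), NIPALS
    partial least squares and univariate band calibration; and spatial
    analyses (band-intensity gradient maps, z-scan focal-plane selection,
    erfc diffusion-profile fitting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
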