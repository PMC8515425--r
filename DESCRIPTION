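Package: xascov
Title: Pre-Edge Quantification and Ligand Covalency from X-Ray Absorption
    Near-Edge Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative analysis of K-edge X-ray absorption
    near-edge structure (XANES) of metal-sulfide clusters: edge-jump
    normalization, impurity spectral subtraction with re-normalization,
    Savitzky-Golay derivative analysis for edge-feature assignment,
    pseudo-Voigt pre-edge peak fitting with uncertainty estimates, conversion
    of integrated pre-edge intensity to ligand np character of the
    redox-active molecular orbital via the transition dipole integral, and
    Gaussian broadening of calculated stick spectra for overlay with
    experiment. Includes a synthetic-spectrum generator with ground-truth
    records so every stage is testable without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    signal,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
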