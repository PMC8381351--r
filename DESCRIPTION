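Package: spectitr
Title: Photoemission Spectroscopy Titration and Site-Specific pKa Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining acid dissociation constants of weak
    polyprotic acids from liquid-jet photoelectron spectra. Provides
    spectrum containers with energy calibration and area normalization,
    forward simulation of core-level and valence spectra from vertical
    ionization energies via empirical Gaussian broadening, constrained
    cumulative Gaussian peak fitting, two-basis linear unmixing of
    pH-dependent spectra, rearranged Henderson-Hasselbalch titration
    fitting for pKa estimation, thermodynamic-cycle pKa assembly from
    gas-phase and solvation free energies, Boltzmann conformer
    populations, and a ground-truth-known synthetic data generator for
    validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
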