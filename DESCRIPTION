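Package: chladyn
Title: Polarization-Resolved Ultrafast Spectroscopy of Chlorophyll-Type Chromophores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the ultrafast photophysics of chlorophyll-like
    chromophores with strongly overlapping, non-orthogonal transitions. Builds
    vibronic band systems with Poisson Franck-Condon progressions; generates
    synthetic steady-state excitation/emission anisotropy data and polarized
    transient-absorption (TA) maps from known ground truth; decomposes isotropic
    spectra into polarization-associated components using a rotated-frame angle
    beta that accommodates non-orthogonal transition dipoles; performs global
    kinetic analysis of TA maps (variable projection over exponentially modified
    Gaussian bases, evolution- and decay-associated spectra, F-test model-order
    selection); propagates wavepackets on nested coupled 2D model potentials
    with a split-operator scheme to model inter-band population transfer; and
    implements a biphasic effective-temperature model of intramolecular
    vibrational redistribution and vibrational cooling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
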