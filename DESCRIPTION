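Package: picomass
Title: Mass, Eigenfrequency and Quality Factor of Single Cells from
    Resonating Microcantilevers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models and analysis for picobalance experiments, in which the
    total mass of a single adherent cell is inferred from the eigenfrequency
    shift of a photothermally actuated microcantilever. Implements the
    two-degree-of-freedom lumped-mass model of a viscoelastic
    (Kelvin-Voigt-attached) cell on an oscillating cantilever, the
    closed-form mass readout-accuracy law, simple-harmonic-oscillator sweep
    fitting, beam-position mass correction, ensemble fitting of the readout
    curve to extract the population-average cell eigenfrequency and quality
    factor, whole-cell stiffness and Young's modulus, Coulter-style
    reference masses, and seeded synthetic-data generators for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'lumped-model.R'
    'mass-readout.R'
    'eigenfit.R'
    'reference-mass.R'
    'synthetic-data.R'
    'io.R'
    'pipeline.R'
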