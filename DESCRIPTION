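Package: dmrskit
Title: Deuterium Magnetic Resonance Spectroscopy Simulation, Quantification and Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative deuterium (2H) magnetic resonance spectroscopy
    (DMRS) of metabolizing tracer mixtures. Simulates first-order deuterium reaction
    networks and the 2H spectra they produce, processes free induction decays into
    referenced spectra and region integrals, converts integrals to deuterium
    concentrations against the natural-abundance HDO internal standard, tracks the
    added-deuterium budget, fits mono-exponential conversion kinetics (including
    joint substrate-product fits with a shared rate constant), and fits T1/T2
    relaxation times from inversion-recovery and CPMG series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    methods,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
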