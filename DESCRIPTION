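Package: fluordimer
Title: Conformational Free Energies of Asymmetric Dimers from 1D 19F NMR
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies conformational free-energy differences between the
    two monomer positions of an asymmetric homodimer (the SMR transporter
    EmrE and its variants) from one-dimensional 19F NMR spectra. Provides
    the binomial statistical-mixing model for labeled/unlabeled monomer
    pairing, a Lorentzian forward spectrum model and seeded synthetic-data
    generator, nonlinear least-squares spectral deconvolution with
    overlap-aware species integrals, overlap-corrected equilibrium
    constants, free-energy decomposition into mutation and fluorine-label
    contributions with error propagation, replicate combination, and a
    manifest-driven command-line pipeline with a parameter-recovery
    harness.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
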