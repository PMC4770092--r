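Package: lidforce
Title: Mechanics and Energetics of Substrate-Dependent Lid Closing from
    Optical-Tweezers Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of dual-trap optical tweezers experiments on enzyme
    lid-closing mechanics, built around adenylate kinase. Provides worm-like
    chain tether mechanics and the constant-force linker correction, a
    seeded generator of synthetic passive-mode traces and force-distance
    curves, two-state hidden Markov transition detection with
    censoring-aware dwell extraction, global Bell-model fits with
    zero-force extrapolation, ligand-competition binding thermodynamics,
    force- and concentration-dependent fraction-of-full-closing models,
    equilibrium unfolding free energies from force-distance curve
    integration, and projection of two-dimensional lid-opening free-energy
    landscapes onto a one-dimensional coordinate under external load.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
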