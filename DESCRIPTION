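Package: gammatongue
Title: Coupled-Oscillator Modelling of V1 Gamma Synchrony and Perceptual
    Arnold Tongues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a retinotopically mapped sheet of weakly coupled
    Kuramoto phase oscillators representing a patch of primary visual
    cortex driven by textures of Gabor annuli, and links the resulting
    gamma-band synchrony to two-alternative forced-choice figure-ground
    segregation performance. Provides texture stimulus synthesis
    parameterised by contrast heterogeneity and grid coarseness,
    complex-logarithmic retinotopy with eccentricity-scaled receptive
    fields, distance-dependent lateral coupling, session-wise Hebbian
    plasticity of the coupling matrix driven by phase-locking values,
    Arnold-tongue construction and comparison metrics (Pearson, weighted
    Jaccard, Simpson tongue volume, psychometric surfaces, noise
    ceilings), and a synthetic behavioural cohort generator for testing
    the full fitting and cross-validation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
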