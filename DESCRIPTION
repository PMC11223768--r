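Package: peadapt
Title: Perceptual-Error Models of Implicit Visuomotor Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, psychophysical calibration and fitting of
    perceptual-error models of implicit motor adaptation in the error-clamp
    paradigm. Implements the perceptual-error adaptation (PEA) model, in
    which visual, proprioceptive and predictive cues are combined by
    precision weighting and the resulting mislocalisation of the hand
    drives a state-space learning rule, together with two rival accounts
    (proprioceptive re-alignment with saturating visual influence, and
    causal inference of the cursor). Includes a logistic 2AFC observer
    with a PEST adaptive staircase and a gamma-GLM eccentricity law for
    visual uncertainty, multi-start bounded least-squares fitting with
    AIC/R-squared model comparison, and seeded synthetic-data generators
    for adaptation, discrimination, proprioception-probe and
    single-trial-learning experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
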