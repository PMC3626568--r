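Package: monodpulse
Title: Monod Growth Kinetics and Assimilation-Gene Pulses from Plate-Reader Batch Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses the last generation of bacterial batch
    growth under a limiting nutrient. Provides deterministic forward models
    (Monod growth with yield-coupled substrate depletion, a band-pass promoter
    activity model with an enzyme-coupled regulated variant, and a
    phenomenological stationary-entry mode), a synthetic 96-well plate-reader
    data generator with a calibrated replicate noise model, and the inference
    pipeline: replicate averaging, growth rate as the logarithmic derivative of
    OD, growth-arrest detection and abrupt/gradual classification, final-OD
    substrate calibration, instantaneous substrate inference, Monod parameter
    fitting with bootstrap confidence intervals, and promoter-activity pulse
    quantification from GFP reporter channels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
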