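Package: apparentmotion
Title: Apparent-Motion (Dmax) Psychophysics and Motion-Detector Models for Insect Vision
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying the displacement limit (Dmax) of apparent
    motion perception in insects driven by the optomotor response. Generates
    stepped random-chequerboard space-time stimuli, predicts motion detection
    with a spatiotemporal Fourier unaliased-energy model and with a population
    model of Hassenstein-Reichardt correlators in two spatial-tuning classes,
    fits cumulative-Gaussian psychometric functions to ternary behavioural
    trial records by maximum likelihood, extracts Dmax at the 50% point, and
    fits the power law relating Dmax to pattern element size. Includes a
    synthetic trial-record generator, CSV trial I/O, and an end-to-end
    comparison pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
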