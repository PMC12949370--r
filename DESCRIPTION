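Package: serfit
Title: Clonogenic Survival Modelling and Sensitizer Enhancement Ratio Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies clonogenic assay data (plating efficiency, survival
    fractions), fits linear-quadratic, multi-target single-hit and
    two-component dose-response models by Levenberg-Marquardt nonlinear least
    squares, and derives iso-survival doses and sensitizer enhancement ratios
    (SER) with parametric-bootstrap confidence intervals and two-sided
    bootstrap p-values for within- and between-group comparisons. Includes
    DNA damage-foci summaries with equal-variance t-tests, dose-rate
    bookkeeping for HDR brachytherapy sources (particle histories, dwell
    dose rates, a point-source dwell-timeline simulator) and pulsed linac
    delivery (dose per pulse, instantaneous dose rate, inverse-square
    distance matching), and synthetic clonogenic and foci data generators
    that emulate triplicate assay designs with binomial colony noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
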