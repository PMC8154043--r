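Package: leafMFA
Title: Isotopically Nonstationary 13C Metabolic Flux Analysis of Photosynthesizing Leaves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for isotopically nonstationary metabolic flux analysis
    (INST-MFA) of photosynthetic leaf central metabolism. Parses
    compartmentalized atom-transition network models, decomposes them into
    elementary metabolite units (EMUs), simulates mass-isotopologue
    distribution (MID) labeling kinetics during a 13CO2 tracer switch, and
    fits net fluxes, exchange fluxes, pool sizes and inactive-pool dilution
    fractions to MID time courses by variance-weighted nonlinear least
    squares. Partitions non-photorespiratory CO2 release (respiration in the
    light, R_L) among the G6P/OPP shunt, TCA-associated decarboxylations and
    fatty-acid synthesis, tests forced-source hypotheses by goodness of fit,
    and computes confidence intervals by parameter continuation and Monte
    Carlo resampling. Includes gas-exchange (Laisk common-intersection) and
    carbohydrate synthesis-rate estimators, plus a synthetic-data generator
    emulating leaf 13CO2 labeling experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
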