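Package: deboreal
Title: Thermal Restructuring of Benthic Communities from Paired Resurveys
Version: 0.1.0
Authors@R:
    person("Kelp", "Forest Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying climate-driven restructuring of benthic
    macroalgal communities from paired historical/modern quadrat surveys.
    Computes species temperature indices (STI) from latitude-binned coastal
    sea-surface-temperature climatologies, community temperature indices
    (CTI), and a four-process decomposition of CTI change (tropicalization,
    detropicalization, borealization, deborealization) with a depth-bin
    correction for shallow-biased sampling. Includes first-principles
    Bray-Curtis, PERMANOVA, dispersion-homogeneity and SIMPER statistics,
    daily sea-surface-temperature extreme-event detection with
    Mann-Kendall/Sen trend tests and smoothing-based warming rates, and
    synthetic-data generators with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
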