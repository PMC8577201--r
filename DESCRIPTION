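Package: rhizoN
Title: Root Hair Phenotypes and Nitrogen Acquisition: Simulation and
    Trial Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale functional-structural simulation of nitrogen uptake
    by maize seedling root systems with explicit root-hair surface area,
    buffered nitrate/ammonium diffusion on a voxelized soil grid, and
    transpiration-driven mass flow; full factorial sweeps over root hair
    length, root hair density, nitrogen supply and transpiration fraction.
    Companion generators produce synthetic greenhouse (RCBD) and field
    (split-plot) recombinant-inbred-line trial data with configurable
    effect sizes, and the statistical chain used to analyse such trials:
    blocked two-way ANOVA, protected LSD groupings, per-treatment linear
    and quadratic regression, and regression-endpoint percent change.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
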