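Package: n15budget
Title: Nitrogen-15 Tracer Mass Balance for Maize Grain Nitrogen Sources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Implements the whole-plant nitrogen-15 tracer mass balance used
    in dual-phase (vegetative/reproductive) pulse-chase labelling experiments
    on maize: exact delta-notation to atom-fraction conversions, tracer dose
    stoichiometry, attribution of grain nitrogen to pre-silking
    remobilization versus post-silking uptake, per-organ partitioning of
    post-silking nitrogen, yield-component and leaf-area phenotype
    arithmetic, a synthetic experiment generator with per-plant ground truth
    for parameter-recovery testing, and treatment-cell aggregation and table
    reporting for nested factorial designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
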