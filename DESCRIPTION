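Package: poultrykpi
Title: Phase-Quality KPIs and Decision Support for Broiler Production
    Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes the 32 phase-quality key performance indicators
    (KPIs) of a broiler production chain from time-stamped sensor data:
    temperature-deviation and heat-stress-index exposure fractions for
    the breeding phase, wristband accelerometer aggregates for the
    loading phase, thermal-comfort fractions and a smoothed z-score
    peak-detection abruptness score for the transport phase, and a
    validated reader/writer for operator-recorded slaughterhouse
    inspection sheets.  A decision-support layer fits classification
    trees to historical chain KPI tables, extracts their rules in
    disjunctive normal form, and filters those rules into actionable
    recommendations.  Seeded generators with planted ground truth
    simulate every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
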