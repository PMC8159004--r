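Package: cvdshock
Title: Unemployment Shocks and Cardiovascular Disease Burden via
    Multi-State Life-Tables
Version: 1.0.0
Authors@R:
    person("Population Health", "Modelling Group", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Propagates scenario-based unemployment shocks into
    cardiovascular disease (CVD) burden for an ethnically stratified
    population. Aggregate unemployment-rate increments are disaggregated
    into ethnicity-, sex- and age-specific absolute changes that preserve
    pre-shock relative rates, converted into relative risks on coronary
    heart disease and stroke incidence, and run through a proportional
    multi-state life-table to produce discounted health-adjusted life
    years (HALYs), health-system costs, per-capita rates and ethnic
    equity ratios, with Monte-Carlo uncertainty intervals. Includes a
    seeded synthetic-data generator emulating the joint structure of
    census population counts, labour-force statistics and burden-of-
    disease epidemiology tables, so the full pipeline is testable
    without access to administrative data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
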