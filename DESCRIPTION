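Package: aclcea
Title: Cost-Effectiveness Analysis of ACL Reconstruction Versus Conservative Treatment
Version: 0.1.0
Authors@R:
    person("Balgrist", "Modelling Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A config-driven cohort decision-tree model comparing surgical
    reconstruction with conservative treatment of anterior cruciate ligament
    (ACL) rupture from a third-party-payer perspective. Pools study-level
    activity-class evidence into arm-specific activity distributions, builds
    direct-cost profiles from resource line items, maps Gottlob activity
    classes to utilities via a calibrated transformation key, rolls back
    two-strategy decision trees, computes incremental cost-effectiveness
    (ICER), net monetary benefit and worst-case scenarios, and runs Monte
    Carlo probabilistic sensitivity analysis with cost-effectiveness
    acceptability curve and frontier outputs. Includes a synthetic-data
    generator for study tables, expert utility surveys and resource line
    items, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
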