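Package: masldcea
Title: Cost-Utility Analysis of Two-Stage Pediatric MASLD Screening Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-utility model for waist-to-height-ratio
    (WHtR) based two-stage screening of metabolic dysfunction-associated
    steatotic liver disease (MASLD) in children. A decision-tree screening
    cascade (WHtR followed by ultrasound, FibroScan or MRI-PDFF) feeds a
    five-state (F0-F4) annual-cycle Markov cohort model of liver fibrosis
    progression and regression under natural history or lifestyle
    intervention. The package accrues discounted costs and quality-adjusted
    life years, computes incremental cost-utility ratios and
    dominance/frontier decisions at willingness-to-pay thresholds, and runs
    one-way, two-way, scenario and probabilistic sensitivity analyses with
    cost-effectiveness acceptability curves. A synthetic-cohort module
    generates age-specific prevalence profiles and provides an independent
    per-individual microsimulation oracle for validating the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
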