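Package: rwgscea
Title: Cost-Utility Analysis of Rapid Genome Sequencing in Pediatric
    Intensive Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for retrospective cost-utility analysis of
    rapid whole genome sequencing (rWGS) in the pediatric intensive care
    unit. Implements modified-Delphi consensus scoring of counterfactual
    care trajectories on a five-point Likert scale, counterfactual
    cost-ledger accounting of avoided and incurred care costs gated by
    panel consensus, probability-weighted decision-tree evaluation of
    quality-adjusted life years (QALYs) with optional annual discounting,
    and cohort-level aggregation to a net cost, incremental
    cost-effectiveness ratio (ICER) and willingness-to-pay value class.
    Ships a reference cohort of 38 PICU probands reproducing published
    cohort totals, and a synthetic cohort generator with known truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
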