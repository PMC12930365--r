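Package: splicescreenr
Title: Two-Tier Yeast Growth and Splicing-Reporter Screen Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-tier small-molecule screens in
    engineered yeast: plate-level quality control (Z-prime factor,
    Bland-Altman replicate agreement), DMSO-normalised growth-inhibition
    hit calling with replicate policies and strain-selectivity
    partitioning, classification of splicing modulators from dual
    SPLIF/SPLOOF fluorescent-reporter kinetic traces by a
    consecutive-cycle persistence rule, compound triage (Lipinski rule
    of five, PAINS pass-through), and RT-PCR percent-spliced
    quantification with Welch tests. Includes a calibrated synthetic
    plate-data simulator (logistic growth, Hill dose-response,
    reporter-coupled fluorescence) so every stage is testable against
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
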