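Package: trialcua
Title: Trial-Based Cost-Utility Analysis for Conservative Incontinence Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic, societal-perspective cost-utility analysis of a
    two-arm trial of app-delivered pelvic floor muscle training for stress
    urinary incontinence, over a 1-year horizon. Scores the ICIQ-UI SF and
    ICIQ-LUTSqol questionnaires, maps responses to a health-state
    classification and preference-based utility weight, computes
    quality-adjusted life years by area under the utility trajectory,
    builds an annualized unit-price cost model with arm-specific
    extrapolation of training time, derives incremental cost-effectiveness
    ratios with dominance classification, and re-runs the analysis under
    one-way and multiway deterministic sensitivity scenarios. Includes a
    reproducible synthetic two-arm trial generator so the full pipeline
    runs end-to-end without external data.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
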