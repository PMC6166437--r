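Package: reportratio
Title: Paired Survey-Mode Reporting Ratios for Pregnancy Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Within-subject comparison of pregnancy-outcome reporting between a
    self-administered count module (ACASI) and an interviewer-administered
    pregnancy history (face-to-face interview). Computes reporter ratios per
    outcome (birth, miscarriage/loss, abortion) over matched recall windows,
    percentile-bootstrap confidence intervals and bootstrap difference tests,
    expanded-window variants probing date misdating, demographic
    stratification, and a lifetime-confusion sensitivity analysis. Includes a
    synthetic-cohort generator with per-event ground truth that emulates
    mode-specific disclosure, date misdating, forward telescoping, and
    lifetime-for-window confusion, so the full pipeline is testable without
    restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
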