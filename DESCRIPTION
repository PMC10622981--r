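Package: rorcase
Title: Case/Non-Case Disproportionality Analysis with Synthetic Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance case/non-case disproportionality
    studies of spontaneous adverse-event reports: MedDRA-style term query
    resolution and case labelling (including DSM-5 neurocognitive domain
    sub-outcomes), cohort restriction with flow-chart accounting, crude and
    age-adjusted reporting odds ratios (Woolf, Mantel-Haenszel and logistic
    regression) with minimum-report and signal rules, subgroup and
    sensitivity analyses, and a seeded generator of synthetic individual
    case safety reports with known ground-truth conditional odds ratios and
    deliberate age confounding, so that every pipeline stage is testable
    without access to a proprietary reporting database.
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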