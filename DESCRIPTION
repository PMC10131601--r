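Package: pupmatch
Title: Propensity-Matched Pre-Post Evaluation of Health-Care Spending
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for retrospective, propensity-score-matched, two-group,
    pre-post evaluation of interventions on health-care spending from
    administrative claims. Implements rolling-enrollment (month-by-month)
    1:1 nearest-neighbor matching within exact segments, ensemble propensity
    scoring, covariate balance diagnostics, 99th-percentile spend capping,
    per-user-per-month (PUPM) difference-in-differences estimation, cost-category
    decomposition, and probabilistic emergent/non-emergent emergency-department
    visit classification. Ships a synthetic claims generator with self-selection
    and an injectable treatment effect so the full pipeline is testable without
    access to proprietary claims.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    stats,
    utils,
    xgboost,
    Matrix,
    generics
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
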