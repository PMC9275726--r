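Package: esrcurve
Title: Rapid Erythrocyte Sedimentation Rate Estimation from Syllectogram
    Aggregation Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the 1-hour Westergren erythrocyte sedimentation rate
    (ESR) from a few seconds of stopped-flow light-transmission data. The
    package computes windowed aggregation indices from syllectograms, corrects
    them for hematocrit, and maps the corrected index through a modified
    Stokes' sedimentation model (Richardson-Zaki hindered settling plus
    exponential aggregate growth) to a full three-phase sedimentation curve
    and its 1-hour value. It also performs the inverse analyses - extracting
    sedimentation velocity, aggregate size parameter, and aggregation time
    constant from measured Westergren time-distance series - fits the
    calibration constants from cohort data, and generates seeded synthetic
    cohorts with known ground truth for validation.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    pracma,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
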