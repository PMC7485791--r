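Package: fatiguerisk
Title: Driver Autonomic Fatigue and Rear-End Collision Risk Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking truck-driver autonomic fatigue,
    measured by heart-rate-variability spectral indices, to rear-end
    collision risk derived from automotive warning events. Provides
    quality control and Welch/Lomb-Scargle spectral analysis of short
    resting RR-interval recordings, the age- and heart-rate-normalised
    LF deviation score, rule-based and CART classification of warning
    events into collision-risk situations, per-hour daily risk indexing
    with short-shift exclusion, and Pearson/Welch association analyses
    between fatigue indices and next-day risk. A synthetic cohort
    generator with known ground truth makes every stage testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rpart,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
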