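Package: accuprofile
Title: Accuracy Profiles and Total-Error Validation of Analytical Methods
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Validation of quantitative analytical methods by the total-error
    (accuracy-profile) approach: per-level trueness, repeatability and
    intermediate precision from a balanced series-by-replicate design,
    beta-expectation tolerance intervals with Satterthwaite degrees of
    freedom, accuracy and linearity profiles with LLOQ/ULOQ decisions,
    calibration response-function fitting with inverse prediction and
    regression-based limits of detection, dissolution-profile evaluation
    against USP Q-criteria with paired method comparison, and timing and
    consumption arithmetic for zone-fluidics analytical sequences. Includes
    a synthetic-data generator emulating the multi-series validation design
    so the full pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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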