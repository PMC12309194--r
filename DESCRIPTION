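Package: oryxseasons
Title: Empirical Season Delineation from Ungulate GPS Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for delineating movement-defined seasons from GPS
    collar data on large desert ungulates. Provides quality-control filters
    for raw collar positions (fix quality, timestamp, speed, and
    deployment-window rules), computation of mean daytime hourly movement
    rates, a day-level reproductive-state labeller driven by calving
    records, penalized-likelihood generalized additive mixed models of log
    movement rate over the calendar year with cyclic smooths and
    autoregressive errors, and a global-mean-crossing procedure that turns
    the predicted population-level curve into season boundaries. A
    synthetic cohort generator with a known latent seasonal profile makes
    every stage testable without access to sensitive tracking data.
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
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
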