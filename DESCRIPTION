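Package: surv2stage
Title: Two-Stage Phase II Trial Designs with a Survival Endpoint under
    Restricted Follow-Up
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design of single-arm two-stage phase II clinical trials whose
    primary endpoint is survival through a clinically meaningful follow-up
    time. The one-sample log-rank test is used at an interim futility look
    and at the final analysis; its exact means, variances and correlation
    under restricted (administrative) follow-up are obtained by numerical
    integration for Weibull event-time models, and operating characteristics
    follow from the asymptotic bivariate-normal law of the two test
    statistics. The package searches for minimax and null-optimal designs,
    verifies and calibrates their power by trial simulation under uniform
    accrual, and provides exact-binomial Simon two-stage designs (with or
    without interim accrual) as comparators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
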