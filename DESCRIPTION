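Package: hragree
Title: Agreement Analysis for Wearable Heart-Rate Monitors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Validates consumer heart-rate wearables against a criterion
    (chest-strap) device. Synchronises and epochs two heart-rate streams,
    removes spike artefacts, fits a repeated-measures Bland-Altman model
    with a participant random intercept (profile REML, optional AR(1)
    residual correlation), derives limits of agreement from the total
    variance with cluster-bootstrap confidence intervals, and summarises
    absolute error by exercise-intensity zone. Includes a synthetic-data
    generator that emulates a graded treadmill protocol so the whole
    pipeline is testable without any device export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools,
    sandwich,
    generics
Suggests:
    testthat (>= 3.0.0),
    lme4,
    nlme,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
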