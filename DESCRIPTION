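Package: posuse
Title: Public Open Space Use from Paired GPS and Accelerometer Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures adolescents' public open space (POS) use from paired
    GPS fix logs (30 s) and accelerometer count logs (15 s): epoch fusion,
    plausibility filtering, Evenson intensity classification, non-wear
    detection and valid-day selection, speed-band transport-mode
    classification, home/school/leisure domain segmentation with 100 m
    buffers and class timetables, POS-visit extraction with inbound and
    outbound trip attribution, per-participant aggregation, and two-part
    multilevel hurdle models (logistic occurrence, gamma log-link amount,
    school random intercept) with covariate screening and a four-step
    model-building procedure. Includes a synthetic-cohort generator with
    full ground truth for known-answer testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmmTMB,
    xml2
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
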