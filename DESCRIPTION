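Package: tempagree
Title: Agreement Analysis for Continuous Paired Core-Temperature Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Method-comparison toolkit for continuous paired temperature
    monitoring, built around repeated-measures Bland-Altman limits of
    agreement estimated by Zou's variance-component method with MOVER
    confidence intervals. Includes per-stream cleaning rules for probe
    dislocation artifacts, a five-zone clinical error grid for
    hypothermia/hyperthermia decisions, precision-based sample-size
    planning for limits of agreement, and a synthetic generator of paired
    intraoperative temperature cohorts for validation and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    sandwich,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
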