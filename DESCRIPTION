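Package: wbpleth
Title: Breath Segmentation and Obstructive Event Detection for Murine
    Whole-Body Plethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyzes continuous box-flow recordings from whole-body
    plethysmography of mice. Segments the flow signal into breaths,
    detects inspiratory flow limitations (IFLs) against 100-breath
    running baselines with a dual z-score criterion, calls IFL
    aggregates (3 or more consecutive flow-limited breaths) and apneas
    (flow cessation of at least 1 s), and summarizes event frequencies
    per hour and per breath with an abnormality cut-off derived from
    control animals. Includes a seeded synthetic-recording generator
    with ground-truth event logs for detector validation, comparative-Ct
    qPCR and densitometry quantifications, morphometry helpers, and a
    normality-gated two-group statistics layer (Student's t /
    Mann-Whitney, chi-square, linear regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
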