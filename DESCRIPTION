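Package: proestimand
Title: Estimand-Aligned Analysis of Longitudinal Patient-Reported Outcomes
    in Single-Arm Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Defines, estimates and reports estimands for longitudinal
    patient-reported outcomes (PROs) in single-arm oncology trials with
    intercurrent events (death, disease progression, treatment
    discontinuation). Provides a discrete-cycle trial simulator with known
    ground truth, a six-state description of PRO availability,
    event-conditioned single imputation, product-limit survival companions,
    and per-cycle mean quality-of-life estimation under while-alive,
    composite, hypothetical and treatment-policy strategies via
    independence-working-correlation GEE and linear mixed models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    grDevices,
    survival,
    lme4,
    sandwich,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    patchwork
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
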