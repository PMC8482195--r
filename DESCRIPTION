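Package: vitalval
Title: Validation Pipeline for Continuous Vital-Sign Wearables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agreement analysis for paired heart-rate and respiratory-rate
    streams from a wearable test device and a bedside reference monitor.
    Implements synchronized 40-second centered-median windowing of multirate
    recordings, mean absolute error and root mean square error with
    percentile-bootstrap confidence intervals, Bland-Altman mean bias with
    95% limits of agreement, Pearson correlation, clinical-acceptance
    evaluation against configurable thresholds, and stratification of a
    controlled-hypoxia phase into oxygen-saturation subgroups. A synthetic
    session generator emulates the movement and desaturation protocols of a
    wearable validation study with known ground truth, so the whole pipeline
    is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    patchwork,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
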