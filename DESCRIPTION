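Package: sepsiswatch
Title: Early Sepsis Prediction in the ICU with False-Alarm-Aware Warnings and Alerts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end early-warning pipeline for hospital-acquired sepsis in
    intensive-care patients recorded as hourly multivariate time series in the
    PhysioNet/CinC 2019 pipe-separated (PSV) dialect. Provides time-limited
    sample-and-hold imputation, min-max rescaling to [1,5] with a -1 sentinel for
    missing values, derived clinical features (shock index, BUN/creatinine ratio,
    MEWS, partial SOFA), a compact masked LSTM sequence classifier over sliding
    4x21 feature windows, a sliding-window warning/alert system that trades alarm
    fatigue against sensitivity, comparator severity scores (SIRS, NEWS, MEWS,
    pSOFA), the timeliness-aware normalized utility score, and a synthetic ICU
    cohort generator so the whole pipeline is testable without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
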