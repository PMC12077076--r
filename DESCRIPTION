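Package: megsni
Title: Synchronous Neural Interactions from MEG Sensor Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes synchronous neural interactions (SNI) -- Fisher
    z-transformed zero-lag partial cross-correlations between prewhitened
    magnetoencephalography (MEG) sensor time series -- and uses them as a
    classification biomarker. Provides ARIMA prewhitening of multichannel
    recordings, partial-correlation network estimation from the precision
    matrix, per-sensor min/max SNI feature extraction, stepwise linear
    discriminant analysis with Wilks' lambda entry/removal tests,
    leave-one-out cross-validation with selection inside each fold,
    Mahalanobis distance classification with normalized distances, severity
    score association statistics, and a synthetic multichannel cohort
    simulator with planted connectivity effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
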