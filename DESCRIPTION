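Package: optifib
Title: Optical-Sensor Surrogate Models for Fecal and Human-Associated
    Indicator Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts in-situ optical fluorescence sensor time series into
    continuous estimates of fecal-indicator and human-associated indicator
    bacteria concentrations in urban streams. Provides fouling, drift,
    temperature and turbidity corrections for field fluorometers; left-censored
    Gaussian (Tobit) regression on log10 concentrations with seasonal
    interaction terms and Duan smearing back-transformation; repeated k-fold
    cross-validation model selection by median prediction error; continuous
    10-minute concentration estimation with combined-sewer-overflow model
    switching; daily load integration, sewage-proportion and annual
    sewage-volume estimation; and comparison against recreational
    water-quality criteria (single-sample and 30-day geometric-mean/STV
    rules). A seeded synthetic-data generator emulates the structure of a
    year-long urban deployment so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
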