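Package: openspiro
Title: Simulation and Analysis for an Open-Architecture Mobile Spirometer
    and Exhaled-Breath Monitor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A virtual-device model and analysis pipeline for a dual-range
    differential-pressure (pneumotachograph) mobile spirometer with
    electrochemical exhaled-gas sensors for nitric oxide and carbon
    monoxide.  Provides forward and inverse sensor transduction with
    dual-range fusion, a physiologically structured breath-session
    simulator with healthy/asthma/COPD phenotypes, flow and volume
    reconstruction with back-extrapolated time zero, spirometry metrics
    (FEV1, FVC, PEF, FET, BEV), ATS/ERS-style acceptability and
    repeatability grading, breath-gas quantification and sensor
    calibration diagnostics, and device-agreement benchmarking
    statistics (Pearson correlation, Bland-Altman limits of agreement,
    two-factor analysis of variance).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
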