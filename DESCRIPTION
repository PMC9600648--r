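Package: shesd
Title: Seasonal Hybrid ESD Detection of High Hospital Admission Days
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classifies anomalously high days in daily hospital admission
    and readmission count series with the Seasonal Hybrid Extreme
    Studentized Deviate (S-H-ESD) procedure: robust seasonal-trend
    decomposition (STL) followed by an iterative generalized ESD test in
    which the sample mean and standard deviation are replaced by the
    median and scaled median absolute deviation.  Includes a uniform
    jitter extension for low-count discrete series whose MAD is zero, two
    comparator detectors (a rolling trimmed-mean/SD rule with a
    quantile-quantile threshold, and a GAM-based 4-SD residual rule), a
    calibrated synthetic admissions generator with ground-truth anomaly
    injection, and detector-agnostic evaluation utilities (sensitivity,
    positive predictive value, seasonal and time-trend summary tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mgcv,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
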