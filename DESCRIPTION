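Package: mwdensity
Title: Frequency-Based Breast-Density Classification from Microwave S21 Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for classifying breast density from multistatic microwave
    transmission measurements. Reads and writes complex S21 scan matrices
    (10 transmitters x 80 receivers x 1601 frequency points, 1-9 GHz),
    removes per-receiver DC bias, extracts dual-domain (angular and spectral)
    FFT magnitude and phase statistics over selectable 1 GHz sub-bands, and
    evaluates classifiers with a Monte-Carlo plus k-fold harness scored by a
    balance-rate metric that penalises unequal class-wise accuracy. Includes
    a moment-calibrated synthetic scan generator whose spatial magnitude
    statistics reproduce published class-wise standard-deviation and
    coefficient-of-variation anchors, and a density-stratified cancer
    detection harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    readr,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    e1071,
    class,
    rpart,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
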