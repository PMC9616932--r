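Package: eegpsd
Title: Automated Resting-State EEG Spectral Features and Group Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A fully automated pipeline for resting-state EEG group studies:
    montage selection, resampling, zero-phase band-pass filtering, 1-s
    epoching, per-epoch artifact screening with a clean-duration gate,
    periodogram power spectral density with 3-30 Hz relative-power
    normalization, band power summaries, t-test-guided feature selection, and
    stratified cross-validated logistic regression. Includes a synthetic EEG
    cohort generator (1/f background, band-limited oscillations with
    group-dependent weights, injectable ocular and muscle artifacts with
    ground-truth masks) so the whole pipeline is testable without clinical
    data. All tabular results are tibbles; fitted results have tidy() and
    glance() methods and ggplot2 plot functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
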