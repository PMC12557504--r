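Package: neurolens
Title: Decoding Persistent Psychological Lenses from Stimulus-Locked fNIRS Timeseries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting hidden, persistent
    psychological "lenses" (e.g. feeling overwhelmed at work) from
    stimulus-locked functional near-infrared spectroscopy (fNIRS)
    recordings. Implements the fNIRS cleaning chain (dispersion-based
    channel rejection, motion-spike removal, zero-phase bandpass
    filtering, modified Beer-Lambert conversion, autocorrelation quality
    control, ROI averaging and 1-Hz resampling), balanced dichotomization
    of Likert outcomes with minority upsampling, multitimepoint pattern
    analysis (MTPA): elastic-net temporal feature selection with
    selection-then-refit logistic classification under repeated
    leave-one-out cross-validation, maximal-statistic permutation
    inference across region-outcome pairs, and reverse-engineering of
    stimulus content at highly selected timepoints via odds ratios with
    circle-shift permutation tests. A synthetic-cohort generator with a
    forward optical model provides ground-truth data for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
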