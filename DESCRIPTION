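Package: morphsong
Title: Form-Function Analysis of Cricket Wing Morphology and Acoustic Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An analysis pipeline linking cricket wing morphology (form) to the
    acoustic structure of male songs (function). Provides spectral feature
    extraction for calling and courtship songs (dominant frequency, RMS
    amplitude, band-relative amplitudes and frequency evenness), landmark
    morphometrics with generalized Procrustes alignment and wing structure
    measurements, morph discovery by Ward.D2 hierarchical clustering with
    gap-statistic model selection, within-morph form-function correlation
    analysis, receiver detectability models on audiogram-style threshold
    curves, Firth penalized logistic regression for phonotaxis outcomes, and a
    seeded synthetic cohort generator producing songs, wings and phonotaxis
    trials with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    car,
    ape,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
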