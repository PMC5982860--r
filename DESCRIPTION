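Package: wristfall
Title: Fall Detection from Wrist-Worn Accelerometer Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold-based fall detection on the acceleration magnitude of a
    wrist-worn triaxial accelerometer. Detects candidate impact peaks, extracts
    eight fall-dynamics features (impact duration, peak and valley magnitudes,
    activity ratio, free-fall index, step count and related indices), balances
    the resulting event dataset with SMOTE, tunes the peak threshold by genetic
    algorithm or simulated annealing with a geometric-mean fitness, and
    evaluates classifier families (neural network, SVM, decision-tree committee,
    rule list) under participant-wise cross-validation, including end-to-end
    recording-level validation. Ships a synthetic-signal generator emulating
    per-participant fall and activities-of-daily-living recordings so the whole
    pipeline is testable without external datasets, and a rank-based comparison
    of fall-feature distributions between datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    kernlab,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
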