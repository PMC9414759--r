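Package: ffhrisk
Title: Pre-Impact Fall-from-Height Risk Prediction from IMU Sensor Windows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates trunk-worn 6-axis IMU recordings for 25 construction-site
    movement types (non-fall work, low-hazard ground-level falls, and
    high-hazard falls from height), extracts the 0.5 s pre-impact feature
    window ending 0.2 s before the acceleration peak, and trains four small
    neural regressors (1D-CNN, 2D-CNN, LSTM, Conv-LSTM; batch size 1, early
    stopping, grid search over layer sizes) to predict the impact peak
    acceleration in g. Predicted peaks are thresholded at 9 g to classify
    fall-from-height risk, with MAE/MSE regression errors, confusion-matrix
    metrics, and per-movement true-versus-predicted summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
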