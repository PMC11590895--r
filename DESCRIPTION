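Package: calfIMU
Title: Collar-Mounted IMU Behavior Classification for Pre-Weaned Calves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying pre-weaned calf behavior from a single
    collar-mounted six-axis inertial measurement unit (triaxial accelerometer
    in g, triaxial gyroscope in deg/s, 25 Hz default). Implements the full
    pipeline: recording and ethogram-annotation I/O, acceleration and
    angular-velocity magnitude channels, 10 s sliding-window segmentation
    with majority labeling, peak-anchored 31-sample event windows for cough
    detection, time- and frequency-domain feature extraction (dominant DFT
    frequency, interquartile range, zero crossings, signal gradients),
    correlation and tree-importance feature selection, individual-wise
    train/test splitting, SMOTE minority oversampling, leaf-wise
    gradient-boosted tree classifiers for feeding-related actions, postural
    states and cough events, and evaluation (one-vs-rest confusion metrics,
    ROC/AUC, daily time budgets, Cohen's kappa). Includes an annotated
    synthetic IMU simulator so the pipeline is testable end to end without
    farm data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    xgboost,
    rpart,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'calfIMU-package.R'
    'classify.R'
    'evaluate.R'
    'features.R'
    'io.R'
    'magnitude.R'
    'pipeline.R'
    'synthetic.R'
    'windowing.R'
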