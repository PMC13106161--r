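Package: wearHAR
Title: Multimodal Wearable-Sensor Action Recognition and Adaptive Exercise
    Prescription
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for multimodal wearable-sensor
    digital-health studies. Generates labelled 12-channel sensor streams
    (three accelerometer placements plus heart rate, galvanic skin response
    and skin temperature) with a virtual-subject physiology model; provides
    an adaptive preprocessing pipeline (linear resampling, Daubechies-9
    wavelet semi-soft threshold denoising, recurrent-network gap imputation,
    dynamic time warping alignment, sliding-window segmentation and Z-score
    standardisation); a hybrid Transformer-GCN classifier over body-placement
    graphs with subject-level evaluation protocols; federated-averaging
    personalisation; PPO-based exercise-prescription generation with a hard
    heart-rate safety override and rule-based baselines; and trial outcome
    metrics (growth rates, injury rates, group comparisons) for simulated
    intervention studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
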