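Package: gart
Title: Gaze-Based Attention Refocusing Training: Task Engine, Feedback
    Controller, and Multimodal Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Offline, hardware-free toolkit for gaze-contingent attention
    refocusing experiments built around a letter-stream continuous
    performance task (CPT) in a virtual seminar room. Provides the CPT
    stimulus generator and scorer, ray-collider gaze-state classification
    with dwell-time and distractibility metrics, the real/sham gaze-based
    feedback controller, adaptive velocity-based saccade and fixation
    detection, an EEG theta/beta-ratio pipeline using a complex Morlet
    continuous wavelet transform, head actigraphy, mixed-design ANOVAs with
    sphericity corrections, and a closed-loop synthetic participant
    simulator with ground-truth labels so every analysis stage is testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    data.table,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
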