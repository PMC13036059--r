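Package: thermorun
Title: Infrared-Thermography Skin-Temperature Analysis for Treadmill Running
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing calibrated infrared-thermography (IRT) frame
    sequences recorded during treadmill running: radiometric frame and label-mask
    I/O, classical calf and vessel-pattern segmentation (superficial veins versus
    cutaneous perforator vessels), stance-phase frame selection, four
    skin-temperature metrics with Shannon entropies, fusion of thermography with
    heart-rate, oxygen-uptake and core-temperature traces (resampling,
    Savitzky-Golay and zero-phase Butterworth smoothing, rolling medians,
    stage aggregation), derived exercise physiology (Mosteller body surface area,
    metabolic heat production, Dickhuth individual anaerobic threshold, sweat
    loss), and from-scratch reliability statistics (two-way single-measures
    intraclass correlation, repeated-measures correlation with cluster bootstrap
    confidence intervals, Cohen-labelled correlations). A synthetic-session
    generator produces thermogram sequences with ground-truth masks and sensor
    traces so the full pipeline is testable without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    tiff,
    png,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
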