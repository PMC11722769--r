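Package: fogr
Title: Detection, Prediction and Sampling-Rate Analysis of Freezing-of-Gait
    Probability Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing per-foot freezing-of-gait (FOG) probability
    traces from wearable inertial sensors in Parkinson disease. Extracts FOG
    events by thresholding and gap-merging, scores them against video-style
    ground-truth annotations as time-based confusion durations, implements a
    monotonic-rise pre-onset prediction rule with threshold sweeps, computes
    detection accuracy and percent of walking time spent freezing, summarises
    task potency for eliciting FOG, and runs an end-to-end sampling-rate
    degradation study (windowed-sinc resampling, spectral-ratio surrogate
    detector, one-way ANOVA with Tukey HSD). Includes a seeded synthetic
    session generator so every analysis is exercisable without participant
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
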