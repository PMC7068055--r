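Package: oddpupil
Title: Oddball EEG and Pupillometry Analysis with Temporal PCA and
    Default-Prior Bayesian Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A complete psychophysiological analysis pipeline for auditory
    novelty oddball studies that record EEG and pupil diameter concurrently.
    Generates pseudo-randomized oddball designs and synthetic multichannel
    EEG plus binocular pupil recordings with known ground truth; preprocesses
    EEG (Hamming windowed-sinc FIR filtering, two-pass ICA ocular cleaning,
    epoching, amplitude-based artifact rejection) and pupil data (count
    calibration, velocity-based blink detection, baseline-corrected epochs,
    binocular averaging); decomposes event-related waveforms by covariance
    temporal PCA with Horn's parallel analysis and oblique Geomin rotation;
    measures component amplitudes and jackknife 80%-relative peak latencies
    with individual-latency retrieval; and performs frequentist mixed ANOVAs
    alongside default-prior Bayesian model comparison with inclusion Bayes
    factors and JZS t-tests. Includes a unified light-adapted pupil diameter
    model for baseline predictions from luminance, field size, age and
    number of eyes.
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
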