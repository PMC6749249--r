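Package: mosdetect
Title: Rule-Based Detection of Moments of Stress from Wearable GSR and Skin Temperature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects moments of stress (MOS) from wearable galvanic skin
    response (GSR, microsiemens) and skin temperature (degrees Celsius)
    streams sampled at 4 Hz. Implements the full processing chain: Butterworth
    filtering with phasic/tonic decomposition of the skin-conductance signal,
    downsampling to 1 Hz, missing-value imputation, construction of a
    per-second bio-geodatabase, a five-rule weighted ternary scoring system
    with a critical-score decision threshold, geolocation of detections, and
    Getis-Ord Gi* hotspot mapping of MOS ratios on a metric grid. Ships a
    ground-truthed synthetic session generator (skin-conductance responses
    with configurable latency, rise time, half-recovery and amplitude, plus
    delayed skin-temperature drops and GPS tracks with designated stress
    zones) so every stage is testable without sensor recordings, and a small
    command-line front-end for batch runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
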