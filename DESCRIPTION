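Package: fhrcluster
Title: Clustering-Based Fetal Heart Rate Extraction from Single-Channel
    Abdominal ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts the fetal heart rate from a single abdominal ECG
    channel without separating the fetal from the maternal signal.  The
    pipeline combines discrete-wavelet-transform denoising (baseline-wander
    and noise suppression in one decomposition/reconstruction pass),
    detection of RS-peak candidates as local-maximum-followed-by-local-minimum
    events, automatic selection of the classification feature from the
    amplitude distribution of those events, k-medoids clustering with
    ++ initialisation into maternal, fetal and noise clusters, a
    distribution-derived refinement of the fetal cluster, and an RR-interval
    plausibility stage that corrects false positives and false negatives.
    Includes a synthetic abdominal-ECG generator with ground-truth beat
    annotations, readers for plain-text and WFDB records, and beat-detection
    evaluation (sensitivity, positive predictive value, accuracy, F1 at a
    50 ms matching tolerance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
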