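Package: neuroadapt
Title: Offline Simulation of Neuroadaptive Automation from Multichannel
    Neural Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An offline simulation of a passive brain-computer interface for
    neuroadaptive flight automation. The pipeline decodes a pilot's intention
    to recover from a sudden flight-attitude perturbation from multichannel
    neural recordings (MEG-like sensor arrays) and quantifies the time and
    altitude saved relative to the manual control-stick response. It provides
    a ground-truth synthetic data generator, causal band-pass preprocessing
    and epoching, PCA-reduced Infomax independent component analysis with
    fixed-weight projection to held-out sessions, peak-anchored RMS features
    with least-squares probabilistic classification (LSPC), sliding-window
    online detection with faster-than-hand adjudication, and the evaluation
    statistics of the approach: beta-posterior balanced accuracies, signal
    detection indices, permutation-null significance of response-time
    savings, and cross-subject generalization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
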