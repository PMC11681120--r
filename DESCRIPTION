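Package: lierhrv
Title: Heart-Rate-Variability Feature Extraction, Cross-Modality Equivalence
    Testing and Baseline-Calibrated Lie Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Beat detection for electrocardiographic and pulse-wave signals
    (multiscale AMPD peak detection, an energy-based QRS detector, and
    detector-agreement fusion), extraction of 39 standard heart-rate-variability
    parameters (time domain, heart-rate fragmentation, Lomb-Scargle frequency
    domain, Poincare, detrended fluctuation analysis, multiscale entropy) over
    sliding windows, one-sample TOST equivalence testing of paired HRV
    parameters with Cohen's-d margins, and a per-participant lie-detection
    pipeline (baseline calibration, sign-split feature scoring, random-forest
    classification against a majority-vote baseline). Includes an IPFM-style
    synthetic-session generator so the full pipeline is testable without
    recorded data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
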