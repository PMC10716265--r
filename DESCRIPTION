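Package: afhorizon
Title: Near-Term Atrial Fibrillation Risk from AF-Free Single-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts near-term atrial fibrillation (AF) from AF-free
    single-lead ambulatory ECG intervals of 10 minutes to 24 hours.
    Implements the full pipeline: a seeded synthetic ambulatory-ECG
    cohort simulator with paroxysmal AF, ectopy and artifacts; 10-minute
    windowing with signal-quality validity rules; heart-rate-variability,
    ectopic and rhythm feature extraction with ectopic-beat exclusion;
    Box-Cox and exponential feature normalization; a hierarchical deep
    model (1-D convolutional window encoder producing 128-dimensional
    embeddings, followed by a 2-layer bidirectional LSTM sequence scorer);
    per-age-group isotonic probability calibration; and a stratified
    percentile/paired bootstrap evaluation protocol with operating points
    at fixed sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    MASS,
    knitr,
    rmarkdown
Config/testthat/edition: 3
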