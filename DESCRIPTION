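Package: hemiconn
Title: Interhemispheric EEG Connectivity Features for Hemispherotomy Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline relating presurgical scalp-EEG interhemispheric
    asymmetry to seizure outcome after hemispherotomy. Reads 10-20 montage EEG
    (EDF) with annotated wake and sleep segments, band-pass filters (0.5-45 Hz
    Butterworth) and segments recordings into 5-s windows, extracts band-power
    spectral density and Hjorth (activity, mobility, complexity) features per
    electrode, forms pathological-minus-healthy differences over the eight
    homologous electrode pairs, and evaluates a grid of nine small feed-forward
    neural networks under a repeated 70/15/15 holdout protocol with averaged
    confusion matrices. Includes a synthetic-EEG cohort generator with a
    controllable interhemispheric-asymmetry effect size for calibration and
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    signal,
    nnet,
    withr
Config/testthat/edition: 3
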