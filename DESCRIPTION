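Package: chronet
Title: Temporal Causal Discovery and Live-Cell Feature Extraction for
    Time-Lapse Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns time-unfolded, translation-invariant causal networks from
    multivariate, mixed-type time series using penalized information-theoretic
    independence tests, with forward pre-orientation of lagged edges,
    probabilistic v-structure orientation and detection of time-lagged latent
    common causes.  Includes a live-cell time-lapse feature extractor (circular
    Hough cell detection, optimal-assignment tracking, morphodynamic and
    cell-cell interaction descriptors), synthetic benchmark generators for
    ground-truthed time series and microscopy videos, and scoring utilities
    (precision, recall, F-score) for learned temporal graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
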