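Package: nrr
Title: Respiratory Rate Extraction from Neonatal NIRS Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts respiratory rate (RR) from raw neonatal near-infrared
    spectroscopy (NIRS) intensity signals. Implements a two-stage algorithm
    that estimates a per-measurement heart-rate frequency band from a
    multitaper (Slepian) spectrum, detects motion artifacts with a
    sliding-window interquartile-range statistic, and tracks the dominant
    respiratory frequency per 30-second segment inside an adaptive band
    proportional to the estimated heart rate. Also provides two comparator
    extractors (fixed band-pass filtering and a baseline-wander
    reconstruction), a Bland-Altman style agreement-evaluation suite, a
    sensitivity-analysis grid, and a synthetic neonatal-NIRS generator with
    known heart-rate/respiratory-rate ground truth so the full pipeline is
    testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
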