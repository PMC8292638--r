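Package: vtekit
Title: Trajectory and Hippocampal Oscillation Based Detection of
    Vicarious Trial and Error
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects vicarious trial and error (VTE) behaviors -- pause-and-look
    vacillations at maze decision points -- for rodents performing binary
    spatial choice tasks.  Computes trajectory-based features of choice-epoch
    head-position traces (integrated change in heading angle and its
    session-wise z-score, positional spread, dwell time, sixth-degree
    polynomial fit quality, Fourier coefficient count), hippocampal field
    potential features (theta-cycle asymmetry index, ascending and descending
    durations, cycle-averaged low and high gamma power and their ratio, and
    periodogram power spectral densities), rater-consensus label curation with
    inter-rater reliability, balanced seeded cross-validated classification
    with k-nearest-neighbor and radial-basis-function support vector machine
    models, chance-referenced evaluation statistics, and a synthetic plus-maze
    behavior and field-potential simulator so that the full pipeline can be
    exercised without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mgcv,
    quadprog
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
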