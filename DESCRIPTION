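Package: elsrtl
Title: Extended Least-Squares Classifiers with Inductive Transfer for Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form regularized least-squares classification in a hidden
    mapping space, instantiated with random-sigmoid neural features,
    Takagi-Sugeno-Kang (TSK) fuzzy-rule features, or Mercer kernels, together
    with an inductive parameter-transfer variant that imports a source-domain
    weight vector through a quadratic penalty. Includes a motor-imagery EEG
    feature front end (time windowing, zero-phase Butterworth band-pass,
    Tikhonov-regularized common spatial patterns, log-variance features),
    seeded synthetic generators for shifted two-domain feature sets and
    oscillatory multichannel trials, and rank-based benchmarking statistics
    (accuracy, tie-averaged rank tables, the Friedman test, and post-hoc z
    comparisons with Holm's step-down correction).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
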