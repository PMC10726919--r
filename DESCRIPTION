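Package: sleepcam
Title: Noninvasive Video Actigraphy Sleep Scoring for Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@sleepcam.dev",
           role = c("aut", "cre"))
Description: Behaviour-based sleep monitoring for laboratory mice. A
    sample-based background-subtraction motion detector converts cage video
    into a per-second foreground-pixel-count trace; an activity threshold and
    the immobility rule (continuous immobility of at least 40 seconds scores
    as sleep) convert the trace into a sleep/wake hypnogram; agreement with an
    EEG/EMG reference hypnogram is summarised with Bland-Altman limits of
    agreement and a consistency coefficient. Includes a synthetic-data module
    (ground-truth hypnograms, motion traces, rendered cage video, imperfect
    reference scorings) so the whole pipeline is testable without animal
    recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    png,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
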