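Package: iinfb
Title: Closed-Loop Mu-Rhythm Neurofeedback Engine for Imagined Imitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable implementation of a real-time imagined-imitation
    (combined action observation and motor imagery) EEG neurofeedback system:
    streaming mu-rhythm (7.5-14.5 Hz) band-power estimation and event-related
    desynchronization/synchronization (ERD/ERS) scoring, a hemisphere-weighted
    neurofeedback score with adaptive difficulty titration, a video-color
    feedback state machine with lockout and EMG gating, yoked sham replay, and
    an offline epoching/ERD analysis pipeline. Includes a closed-loop virtual
    subject simulator (mu oscillations, 1/f background, ocular and myogenic
    artifacts) so the entire engine can be exercised end-to-end without
    recorded human data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    tibble,
    dplyr,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
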