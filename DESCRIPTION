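Package: swdwave
Title: Wavelet-Based Detection and Analysis of Spike-Wave Discharges in
    Rodent EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Offline analysis pipeline for spike-wave discharges (SWDs),
    the electroencephalographic hallmark of absence epilepsy, in chronic
    single-channel rodent EEG. Provides a continuous Morlet wavelet
    transform with 5-32 Hz band-power collapse, robust adaptive
    thresholding and event segmentation with a 1 s duration floor,
    automated broadband-artifact rejection, per-event spectral
    characterization (dominant frequency, harmonic ratio), per-session
    summaries (events per hour, accumulated seizure time, duration
    histograms), stimulus-locked interruption classification, and a
    nonparametric comparison layer (rank-sum, signed-rank,
    Kruskal-Wallis with Dunn-type pairwise follow-up). A calibrated
    synthetic-EEG generator emulates vigilance-state backgrounds and
    spike-wave morphology so that every stage is testable without animal
    recordings. Reads and writes EDF and plain columnar text.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
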