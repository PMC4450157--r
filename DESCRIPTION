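Package: fpvs
Title: Frequency-Tagging Analysis of Fast Periodic Visual Stimulation EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for designing and analysing fast periodic visual
    stimulation (FPVS) oddball EEG experiments. Builds sinusoidal
    contrast-modulation stimulation sequences with periodic oddball
    events, simulates multi-channel EEG cohorts with frequency-tagged
    responses over 1/f background noise, applies the standard
    preprocessing chain (FFT band-pass filtering, Fourier resampling,
    epoch segmentation, channel interpolation, common average
    referencing, analysis-window cropping and per-sequence quality
    control), quantifies responses with neighbour-bin signal-to-noise
    ratios and Z-scores of the amplitude spectrum, and runs group-level
    inference (one-sample and paired t-tests, Bonferroni-corrected
    channel-wise Z-tests, per-subject significance tallies).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
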