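Package: finsong
Title: Fin Whale Song Detection and Structure Analysis for Duty-Cycled
    Passive Acoustic Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for long-term passive acoustic monitoring of fin whale
    (Balaenoptera physalus) song. Generates synthetic duty-cycled
    deployments with ground-truth annotations (20 Hz downsweep notes,
    130 Hz upsweeps, backbeats, ambient and transient noise, a seasonal
    sea-surface-temperature series), detects notes with a spectrogram
    band-energy-ratio detector, aggregates detections into weekly
    presence and detection rates, segments note trains into songs,
    measures inter-note intervals under standard selection rules,
    classifies unimodal versus bimodal (doublet) interval patterns with
    Gaussian mixtures, and fits the seasonal statistical layer
    (cyclic-spline generalized additive models, Spearman correlations
    with temperature, rank-based group contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    mclust,
    mgcv,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
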