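Package: nociburst
Title: Burst-and-Pause Firing and Dendritic Calcium Analysis for
    Nociceptive Sensory Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of burst-and-pause firing in polymodal
    nociceptors and of the dendritic signals that accompany it. Detects
    unconventional spikes (three-spike bursts defined by two interspike
    intervals under 9 ms followed by a pause over 20 ms) in spike-time
    data, quantifies pause periods and firing-rate fluctuations, detects
    dendritic calcium transients with a Schmitt trigger and estimates
    their onsets by bounded multi-start fitting of a double-exponential
    rise-and-decay model, computes ratiometric FRET chloride signals,
    scores dendritic arbor coverage on grid-overlaid micrographs, and
    runs the associated statistical comparisons with multiple-testing
    correction. A seeded synthetic-data generator produces spike trains,
    fluorescence traces, FRET channel pairs, rendered arbors and
    behavioral cohorts with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
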