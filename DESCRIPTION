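Package: picoswallow
Title: Swallow-Breathing Coordination Analysis for Optogenetically
    Stimulated Electromyography Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing swallow-breathing coordination in
    multi-channel electromyogram (EMG) and electroneurogram (ENG)
    recordings during brief optogenetic stimulation of the
    postinspiratory complex (PiCo). Implements the full analysis chain:
    band-pass filtering, rectification and smoothing, ECG artifact
    excision, motor-burst and breath detection, stimulus-evoked behavior
    classification (swallow, laryngeal activation, no response),
    swallow-related metric extraction, respiratory phase-reset curves,
    phase-dependent behavior probability curves, and swallow-timing
    histograms. Includes a seeded synthetic-session generator with
    ground-truth labels that emulates the statistical structure of in
    vivo sessions (rhythmic diaphragm bursts, randomized laser pulse
    trains, phase-dependent all-or-none swallows versus stimulus-locked
    laryngeal activation, ECG contamination, broadband noise) for
    validation and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
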