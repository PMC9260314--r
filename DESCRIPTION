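Package: swacomp
Title: Slow-Wave/Spindle Coupling and the Composition of Slow-Wave Activity in Sleep EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes the slow-wave activity (SWA) of overnight NREM sleep EEG
    into subtypes defined by slow-wave/spindle temporal coupling. Detects slow
    oscillations by zero-crossing half-wave analysis with rank-based amplitude
    selection, detects early-fast (14.5-18 Hz) and late-fast (10-13.5 Hz) sleep
    spindles by envelope thresholding, classifies trough-locked coupling in the
    0.2-1.5 s post-trough window, computes baseline-normalized Morlet wavelet
    time-frequency maps around slow-wave troughs, and summarizes per-night SWA
    composition as time-binned and stage-specific percentages of late-fast
    coupled events. Includes clustered negative-binomial count comparisons,
    repeated-measures region-of-interest power contrasts, event-count-weighted
    t-tests, a minimal EDF reader/writer, hypnogram parsers, and a seeded
    synthetic polysomnography generator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    MASS,
    sandwich,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
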