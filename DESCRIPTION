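Package: ftfa
Title: F-Value Time-Frequency Analysis of Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-univariate one-way ANOVA F-statistics computed at every
    pixel of trial-wise wavelet time-frequency power maps of multichannel
    EEG ("FTF maps"), highlighting the time-frequency features whose power
    differs across experimental conditions. Includes cue-locked epoching,
    complex Morlet wavelet power with per-frequency baseline normalization,
    F-distribution thresholds and significance masks, band-limited scalp
    topographies, minimal EDF input/output, and a paradigm-structured
    synthetic EEG generator with known event-related
    desynchronization/synchronization (ERD/ERS) ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
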