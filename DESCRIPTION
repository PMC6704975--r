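Package: microstater
Title: Resting-State EEG Microstate Analysis with Planted-Truth Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for resting-state EEG microstate analysis: band-pass
    filtering, decimation and average re-referencing of multichannel
    recordings; polarity-invariant modified k-means clustering of scalp
    topographies at global field power peaks; selection of the number of
    microstate classes by a seven-criterion meta-criterion; two-level
    (individual then group) clustering; spatial-correlation backfitting with
    Besag-factor temporal smoothing; per-class duration, occurrence, coverage
    and global explained variance; and the group-comparison and clinical
    correlation statistics used in microstate studies of mood disorders.
    Includes a semi-Markov synthetic-EEG generator with planted template
    topographies so every stage can be validated by parameter recovery, and
    readers and writers for EDF and delimited channel-by-sample matrices.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
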