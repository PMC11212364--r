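Package: epgvars
Title: Calculation of Electrical Penetration Graph Feeding-Behavior Variables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parses waveform-annotated electrical penetration graph (EPG)
    recordings of piercing-sucking insects, checks the annotation sequence
    against the standard waveform-marking guidelines, and computes a
    standardized registry of 127 feeding-behavior variables per recording,
    including non-sequential waveform statistics, sequential times and
    counts, potential indices, and potential-drop (pd) subphase variables.
    Implements the truncated wave criterion, a least-biased estimator of
    median and mean waveform-period duration when the final period is
    artificially terminated by the end of the recording, plus per-hour and
    cumulative temporal analyses, per-event tables, and a synthetic
    recording generator for property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
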