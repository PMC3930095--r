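Package: ephysio
Title: Unit-Aware Object Model and File IO for Electrophysiology Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-memory object model for electrophysiology recordings
    (continuous analog signals, spike trains, events and epochs) in which
    every physical attribute carries explicit units, together with a
    hierarchical container/grouping graph (blocks, segments, recording
    channels, tetrode channel groups, sorted units) and a pluggable
    input/output framework.  The IO layer supports lazy (metadata-only)
    and non-cascading reads, lossless metadata round-trip, and format
    conversion between an HDF5 container, delimited text and raw binary
    recordings with JSON sidecar metadata.  Deterministic generators
    reproduce reference multi-trial probe and two-tetrode example
    datasets for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    R6,
    jsonlite,
    rhdf5,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
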