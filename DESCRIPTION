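Package: chunktag
Title: Frequency Tagging and ERP Analysis of Chunked Syllable Streams
    with Non-Adjacent Dependencies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for artificial-grammar studies of speech chunking and
    non-adjacent dependency (NAD) learning with EEG frequency tagging.
    Generates isochronous syllable-stream designs (6-syllable chunks at
    0.63 Hz with embedded within- or across-chunk dependency pairs),
    simulates multichannel EEG-like recordings with 1/f background noise,
    and analyses them with evoked power, neighbour-normalized evoked
    power, inter-trial phase coherence, and a spatio-temporal
    cluster-based sign-flip permutation test on event-related potentials,
    plus a chunk-aware mean dependency distance metric.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
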