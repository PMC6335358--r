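Package: meanet
Title: Network Activity Analysis for Multielectrode-Array and Calcium
    Imaging Recordings of Neuronal Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying neural-network formation in dissociated
    neuronal cultures recorded on planar multielectrode arrays (MEAs) and by
    calcium imaging. Implements median-based threshold spike detection from
    extracellular voltage, network-burst detection and small/large
    classification from the total spiking rate, delayed-synchrony
    cross-correlation connectivity with distance-proportional axonal delays,
    functional-graph construction with hub metrics and between-session
    overlap, and derivative-threshold calcium transient detection. Includes a
    synthetic-data generator that plants spikes, network bursts, hub-structured
    propagation and calcium transients with full ground truth, so every stage
    of the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
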