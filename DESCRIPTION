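Package: spikeEtypes
Title: Electrophysiological Typing, Event Responses and Synchrony of Spike
    Trains in Probabilistic Pavlovian Conditioning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for extracellular spike trains recorded during
    probabilistic Pavlovian conditioning. Classifies units into
    electrophysiological types from autocorrelogram burst and beta/gamma
    rhythmicity indices, parses spike trains into bursts and single spikes by
    inter-spike-interval rules, quantifies peri-event responses
    (activation/inhibition, latency, expectation contrasts), analyzes
    anticipatory licking, and detects fine-timescale pairwise synchrony and
    putative monosynaptic connections with jitter-surrogate confidence bands,
    grouping synchronous units into co-firing assemblies. Includes a fully
    seeded synthetic-session generator with ground truth so that every stage
    is verifiable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
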