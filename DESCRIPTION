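Package: mitonet
Title: Anchored Gene Co-Expression Networks by Partial Correlation and
    Information Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs gene co-expression networks anchored on a
    predefined gene set (for example, mRNA encoding the mitochondrial
    proteome) from a genes-by-samples expression matrix. Pairwise
    associations are screened with the partial correlation and
    information theory (PCIT) trio-elimination rule, thresholded on
    correlation magnitude, and assembled into an undirected weighted
    network. Provides network topology summaries (degree, connected
    components, diameter-normalized radiality), a counts-per-million
    expression filter, differential-expression overlays with
    cross-contrast consistency queries, transcription-factor network
    augmentation with a connectivity-based retention filter, a seeded
    synthetic-data generator with planted correlation modules, and
    Cytoscape-compatible exporters (edge list, SIF, GraphML).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    graphics,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
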