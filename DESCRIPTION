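Package: hubnet
Title: Multi-Omics Correlation Networks and Hub-Gene Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed Spearman correlation networks from multi-omics
    feature-by-sample abundance matrices and tests whether a focal feature is
    a network hub. Implements blocked exact tie-aware Spearman correlation
    with absolute-value prefiltering, thresholded graph construction with
    degree, closeness and betweenness centralities, a one-sample Wilcoxon
    signed-rank hub test against the network's Hodges-Lehmann pseudo-median,
    half-minimum imputation and wild-type reference normalization,
    Benjamini-Hochberg adjustment with fold-change/FDR differential filtering
    and an enrichment-direction z-score, canalization (scaled absolute
    deviation from the median) and spectrophotometric pigment statistics, and
    a synthetic multi-omics generator with a planted correlated hub module
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
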