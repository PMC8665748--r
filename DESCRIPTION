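Package: loopgcp
Title: Two-Stage Random-Forest Prediction of CTCF-Mediated Chromatin Loops
    Using Network Transitivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts CTCF-mediated chromatin loops from CTCF motif
    occurrences, CTCF/RAD21 ChIP-seq peaks and ChIA-PET loop lists with a
    two-stage random-forest classifier. The first stage scores candidate
    anchor pairs from anchor, motif-sequence, in-between and distance
    features; the predicted probabilities define an edge-weighted chromatin
    interaction network from which a graph connecting probability (GCP) --
    the best product of edge probabilities over alternative paths between
    the two anchors -- is computed and fed to the second stage. Includes
    distance-matched negative sampling, network transitivity statistics
    (clustering coefficients, k-cliques, alternative path lengths,
    degree-preserving nulls), transitive-triple detection with multiway
    contact cluster colocalization testing, and a synthetic data generator
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    ranger,
    pROC,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
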