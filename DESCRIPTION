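Package: retnetdyn
Title: Dynamics of Integrated TF-miRNA Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Construction and dynamic analysis of integrated regulatory
    networks composed of transcription factors, microRNAs and their target
    genes. Builds a typed static network from TF-target and miRNA-target
    edge lists, extracts per-time-point active sub-networks by expression
    thresholding plus backtrack regulator closure, and characterizes their
    dynamics through directed topology metrics (clustering coefficient,
    betweenness, reachability, average path length), typed size-3 network
    motif enrichment against degree- and neighbor-type-preserving edge-swap
    null models, miRNA-target expression-correlation randomization tests,
    hypergeometric functional enrichment with e-values, and hub-removal
    perturbation analysis. Includes a synthetic-data generator emulating a
    developmental time-course study so every stage of the pipeline can be
    exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
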