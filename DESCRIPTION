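Package: perturbnet
Title: Network-Level Analysis of Transcriptomic Perturbations Without Replicates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dose-time transcriptomic perturbation studies
    that lack biological replicates. Provides fold-change based differential
    expression calling, set algebra over per-condition DE gene sets (Venn
    partitions, non-redundant unions, temporal-shift detection), merging of
    pathway graphs (SIF/XGMML) into one biological network with edge
    provenance, permutation tests for degree bias, DE-induced subnetwork size
    and hub capture, two-list hypergeometric gene-set enrichment, and a
    negative-binomial simulator that generates every input with known ground
    truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
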