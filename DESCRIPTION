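Package: phytonet
Title: Network-Pharmacology Screening of Herbal Phytochemicals
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrated network-pharmacology pipeline for screening herbal
    phytochemicals against a disease gene pool (developed around epilepsy):
    path-based molecular fingerprints and Tanimoto similarity, drug-likeness
    and ADMET filtering of phytochemical libraries, consensus voting over
    multiple target-prediction sources, construction and analysis of layered
    herb-compound-protein-drug networks (degree and betweenness centrality,
    power-law degree-distribution fits, native MCODE dense-module detection),
    and the downstream selection cascades: neuromodulatory-protein screening,
    candidate compounds similar to approved drugs, anti-epileptic-drug
    poly-pharmacology overlap, and module-regulator back-mapping. A seeded
    synthetic-data generator with a planted ground-truth sidecar makes every
    pipeline stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
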