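Package: coexhub
Title: Differential Co-Expression Networks and Hub Nomination for
    Perturbation Screens
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nominates core regulatory genes from paired-condition expression
    data by differential-expression filtering, Fisher's exact gene-set
    enrichment with Benjamini-Hochberg false-discovery-rate control,
    condition-specific Pearson co-expression networks with FDR-selected
    edges, degree centrality, k-core decomposition, the differential-degree
    ("Dif degree") hub statistic, and cross-perturbation intersection.
    Includes a synthetic-data generator with planted differential expression,
    co-expression modules and rewired hubs; closed-form quantifications
    (2^-ddCt relative expression, dual-luciferase normalization); phenotype
    proportion scoring; and a deterministic end-to-end pipeline with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
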