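Package: woodnet
Title: Co-Expression Network Analysis of Wood-Formation Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for network analysis of spatially resolved wood-formation
    transcriptomes: mutual-information/CLR co-expression network inference with
    signed edges, betweenness- and closeness-based hub identification and node
    categorization, seed-gene module extraction, a moderated differential
    expression caller for ethylene-responsive genes in a three-genotype by
    two-treatment ACC experiment, hypergeometric gene-set enrichment, and a
    synthetic data generator that emulates a multi-tree stem cryosection
    series and the factorial count experiment with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    limma,
    edgeR,
    fgsea,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
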