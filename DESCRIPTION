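Package: comorbidnet
Title: Disease Network Comparison and Hub-Bottleneck Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-disease protein-protein interaction networks from
    scored edge tables and disease gene sets, identifies hub-bottleneck
    genes by degree (mean + 2 SD) and betweenness (top 5 percent) rules,
    quantifies the overlap between two disease networks (shared genes,
    Jaccard index, hypergeometric significance), and ranks pathway
    over-representation of the shared genes to nominate connector
    diseases and pathways. Includes a seeded synthetic-interactome
    generator with planted hubs, paired gene sets, and planted pathway
    enrichment for benchmarking, plus packaged worked-example tables for
    an Alzheimer's disease versus type 2 diabetes comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
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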