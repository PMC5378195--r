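Package: motivenet
Title: Seed-Based Network Expansion and Permutation GSEA for Proteomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for network-based enrichment analysis of label-free
    proteomic data. Curated "motives" (literature-derived biological processes,
    each a set of seed genes) are expanded over protein-protein interaction
    networks assembled from binary records and spoke/matrix-expanded protein
    complexes, with a publication-aware confidence score and a high-confidence
    filter. Peptide-level quantifications are log2/median normalized,
    summarized to proteins, and tested for differential abundance (Welch t,
    Benjamini-Hochberg). Each motive-derived signature is then scored against
    the log2 fold-change ranking with a weighted Kolmogorov-Smirnov enrichment
    score, a gene-label permutation null, normalized enrichment scores and FDR.
    A synthetic-data generator with planted group effects makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    ggplot2,
    yaml,
    jsonlite
Config/testthat/edition: 3
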