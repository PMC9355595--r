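Package: mirnet
Title: Integrated miRNA-mRNA Regulatory Network Analysis for Bud Dormancy Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for integrated small-RNA and mRNA
    expression analysis of perennial bud dormancy release. Implements
    small-RNA tag filtering and miRNA family assignment, TPM
    normalization and negative-binomial differential-expression
    screening, plant miRNA target prediction under six positional
    duplex-alignment criteria with G:U wobble scoring, degradome
    (PARE) cleavage-site validation with five-category classification,
    weighted co-expression network construction (soft-thresholded
    adjacency, topological overlap, module detection, eigengenes,
    module-trait association, hub selection), hypergeometric term
    enrichment with FDR control, miRNA-transcription-factor regulatory
    network assembly with Cytoscape-compatible export, and dormancy
    phenology utilities (chilling hours, bud break rate, relative
    qPCR expression). A synthetic-data generator with planted modules,
    target sites, and degradome peaks makes every stage testable
    without external sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
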