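Package: neamarker
Title: Network Enrichment Analysis Scores as Robust Pathway-Level Biomarkers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Transforms per-sample altered gene sets into pathway-level
    (PWNEA) and gene-node-level (GNEA) network enrichment z-scores using a
    connectivity-normalized chi-squared null on a global gene interaction
    network. Provides construction of altered gene sets from expression,
    copy-number and point-mutation matrices (fixed-size, significance-based,
    network-filtered and multi-platform combined classes), overrepresentation
    and single-sample GSEA baselines, drug-sensitivity association
    statistics with cross-screen consistency and permutation-based true
    discovery rates, and a synthetic-data module with a degree-preserving
    rewiring null oracle so that every statistic is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), methods
Imports: igraph, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
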