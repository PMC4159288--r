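Package: barcodeAudit
Title: Auditing DNA Barcode Reference Libraries for Species-Level Signal
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing aligned COI-5P DNA barcode reference
    libraries against their species labels. Computes Kimura 2-parameter
    distances with pairwise deletion, per-species divergence summaries and
    nearest-neighbour tables, neighbour-joining trees with nonparametric
    bootstrap and a per-species monophyly audit, single-linkage threshold
    clustering as a documented operational-taxonomic-unit proxy,
    statistical-parsimony haplotype networks with a probabilistic
    connection limit, and a recursive barcode-gap partitioner swept over a
    grid of intraspecific-divergence priors and relative gap widths, from
    which a per-species intraspecific divergence estimator is read. A
    seeded synthetic-library generator plants haplotype sharing and deep
    intraspecific splits so that every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    ape,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'barcodeAudit-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'distances.R'
    'library-io.R'
    'synthetic-data.R'
    'parsimony-network.R'
    'gap-partition.R'
    'tree-cluster.R'
    'audit.R'
    'utils.R'
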