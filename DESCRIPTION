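Package: scmethpipe
Title: Single-Cell Combinatorial-Indexing Bisulfite Methylation Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end processing and analysis of single-cell
    combinatorially indexed bisulfite sequencing experiments: three-index
    barcode demultiplexing with hamming-distance correction and structural
    trimming, barcode-aware PCR duplicate removal, per-cytosine methylation
    calling in CG and merged CH contexts, two-species barnyard doublet and
    crosstalk estimation, cells-by-genomic-window methylation matrices with
    coverage filtering, truncated-SVD plus Louvain clustering, methylome
    coverage saturation analysis, cluster-level region methylation with
    z-scoring, cell-cell methylation concordance, and motif-centered
    methylation profiles. A complete synthetic-experiment simulator with
    recorded ground truth (genomes, cell types, collision doublets, PCR
    duplicates, conversion noise) supports validation without access to
    restricted sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    Matrix,
    igraph,
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
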