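Package: conkatseq
Title: Co-Occurrence Network Analysis of Targeted Amplicons from Partitioned
    Clone Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers which biosynthetic-domain sequence variants are physically
    clustered on the same metagenomic DNA fragments from their joint
    presence/absence pattern across subpools of a highly partitioned clone
    library. Provides barcode demultiplexing of paired-end amplicon reads,
    greedy centroid clustering of domain variants at 95% identity,
    abundance-based filtering, one-sided Fisher's exact tests on variant
    co-occurrence with two-stage Benjamini-Krieger-Yekutieli false-discovery
    rate control, assembly of significant links into domain networks,
    similarity scoring of networks against reference biosynthetic gene
    cluster (BGC) proteins, contig-based validation, coverage-based abundance
    extrapolation, and a synthetic partitioned-library simulator with known
    clustered-domain ground truth for end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
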