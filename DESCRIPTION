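Package: CGRecon
Title: Reconstruction of Complex Germline Genomic Rearrangements from
    Sequencing Breakpoints and Hi-C
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for resolving complex germline genomic rearrangements
    (chromothripsis, chromoplexy) by integrating novel-adjacency calls from
    long-read and short-read sequencing with Hi-C contact maps. Provides
    filtering and merging of breakpoint calls from two technologies,
    construction and traversal of a fragment reconstruction graph to derive
    derivative-chromosome layouts, Hi-C contact-matrix recomposition along a
    reconstruction, grouping/ordering/orientation of incomplete scaffolds via
    an explicit permutation score, junction microhomology and InDel analysis
    from soft-clipped reads, breakpoint-based haplotype labeling with
    allele-specific expression calling, and empirical permutation null models
    for breakpoint enrichment against chromatin-feature tracks. A simulator
    generates fully ground-truthed synthetic inputs for every component.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    igraph
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
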