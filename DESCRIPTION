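Package: apbstools
Title: Architectural Protein Co-Occupancy and Topological Domain Border Strength
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking combinatorial binding of architectural proteins
    (insulator proteins, cohesin, condensin, TFIIIC) to the strength of
    topologically associating domain (TAD) borders. Provides multi-factor
    occupancy segmentation of ChIP-seq peak sets into architectural protein
    binding sites (APBSs) with low/medium/high occupancy classes, a local
    contrast statistic quantifying TAD border strength from restriction
    fragment level Hi-C contact maps, rank-order normalization of binned
    coverage tracks, chromosome-aware Monte Carlo permutation enrichment
    tests, multi-experiment site ubiquity scoring, and seeded synthetic-data
    generators with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
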