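Package: ihscape
Title: Chromatin Heterogeneity of Late-Replicating Intercalary
    Heterochromatin Domains
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the chromatin landscape of intercalary
    heterochromatin (IH), the large late-replicating repressed domains of
    Drosophila euchromatic chromosome arms. Builds chromatin domain maps
    from fragment-level four-state segmentations (gap filling, domain
    merging, per-region composition), computes domain contact topology and
    border/internal malachite classification, quantifies overlap and
    enrichment of annotation tracks against chromatin classes with a
    length-preserving domain/spacer index-shuffle Monte-Carlo permutation
    null, summarises tissue expression breadth by chromatin class, and
    profiles replication timing including the border-to-center timing
    gradient of IH bands. A seeded synthetic-data generator emulates every
    input with planted ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, FunctionalGenomics, Software, StatisticalMethod
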