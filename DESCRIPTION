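Package: tadtriplex
Title: Linking RNA-DNA Triplex-Forming Sites to 3D Genome Organization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating genome-wide RNA-DNA triplex-forming sites of a
    long noncoding RNA to features of 3D chromatin organization. Implements a
    length-preserving interval shuffle null model and a fitted-normal coverage
    enrichment test against topologically associated domains (TADs) and their
    boundaries; a 10-bin positional-occupancy profile within TADs with a
    Kolmogorov-Smirnov comparison to a within-TAD randomized control;
    classification of sites by boundary gain/loss and A/B compartment-switch
    patterns across four ordered differentiation stages with a chi-square
    comparison to randomized sites; per-site profiling against signal tracks
    (ChIP signal, conservation), repeat-class occupancy with boundary versus
    non-boundary grouping and pairwise Welch t-tests, and nearest-TSS target
    assignment. A seeded synthetic-data generator produces complete input
    bundles with planted structure so every pipeline stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
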