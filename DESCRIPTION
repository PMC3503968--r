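Package: ssapdyn
Title: Transposable Element Insertion Polymorphism Dynamics in
    Allopolyploids from Dominant SSAP Markers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of dominant presence/absence marker matrices
    (SSAP, AFLP-like) in allopolyploid species complexes. Classifies
    marker bands by parental origin, scores each polyploid taxon for
    deviation from predicted parental additivity (new and missing
    bands), partitions non-additive bands into sharing categories
    across polyploid taxa, attributes band losses to the maternal or
    paternal progenitor, estimates null-allele frequencies and Nei's
    gene diversity for dominant markers under full inbreeding, and
    builds NeighborNet circular split networks with locus bootstrap
    support. Includes a synthetic-data generator emulating
    allopolyploid marker evolution (segregating parental insertions,
    additive polyploid origin, biased band loss and gain bursts along
    the polyploid subtree) with replayable truth logs, packaged
    reference count tables for the Nicotiana section Repandae SSAP
    survey of seven transposable-element families, and the statistical
    procedures used with such data (Yates-corrected one-sided
    chi-square, Fisher exact, Wilson score intervals, Holm step-down
    correction, one-way ANOVA with Tukey HSD, Mantel tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    vegan,
    phangorn,
    jsonlite,
    knitr,
    rmarkdown
biocViews: Genetics, Phylogenetics, PopulationGenetics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
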