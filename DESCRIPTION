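Package: refstab
Title: Reference Gene Stability Analysis for RT-qPCR Normalization
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A workflow for selecting and validating reference genes for
    RT-qPCR relative quantification. Converts raw quantification-cycle (Cq)
    tables into efficiency-corrected relative quantities with inter-run
    calibration and genomic-DNA contamination screening (ValidPrime-style),
    ranks candidate reference genes by the geNorm expression-stability
    measure M, determines the optimal number of reference genes from the
    pairwise-variation series, quantifies the normalization bias introduced
    by alternative reference-gene sets, partitions expression variance with
    a three-level fully nested random-effects ANOVA, and performs a
    cross-dataset RNA-seq fold-change meta-analysis that classifies
    candidate genes into stability classes by Ward clustering of per-gene
    median and interquartile range. Includes seeded synthetic-data
    generators with planted ground truth so the whole pipeline is testable
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
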