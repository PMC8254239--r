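Package: bsamapr
Title: Bulked-Segregant Analysis Mapping of Recessive Loci from Pooled
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping a single recessive locus from bulked-segregant
    analysis of pooled whole-genome sequencing (BSA-seq) of an F2 population.
    Implements the SNP-index and delta-SNP-index sliding-window statistic with
    depth-block aggregation and null-simulation significance thresholds,
    candidate-region calling, Mendelian segregation chi-square testing,
    candidate-SNP triage under a recessive model (zygosity and shared-promoter
    exclusion rules), relative expression analysis by the 2^-ddCt method, and
    spectrophotometric quantification of chlorophylls and their biosynthetic
    precursors. Includes a fully seeded F2 pooled-sequencing simulator with
    known ground truth for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
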