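Package: cpgdm
Title: CpG Density, Methylation Conservation, and Mutation Effects on Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for relating CpG sequence density to DNA methylation
    conservation between inbred mouse strains and to the transcriptional
    consequences of CpG-disrupting mutations. The package segments a genome
    into fixed-size windows, calls per-site CpG methylation from bisulfite
    read counts, computes cross-strain same-state probabilities and
    methylated-count ratios pooled by CpG density, selects candidate
    methylated-CpG-disrupting variants, and tests whether their effect on
    transcript abundance depends on local CpG density using inverse-normal
    transformed linear models, nested-model F tests, chromatin-state
    stratified scans, permutation calibration, and threshold sensitivity
    sweeps. A seeded synthetic-data generator produces genomes, strain
    methylomes, variant tables, chromatin states, and differential-expression
    tables with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
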