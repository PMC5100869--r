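Package: methylDynamics
Title: Simulation and Analysis of Postnatal DNA Methylation Dynamics from
    RRBS Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying developmental DNA methylation dynamics from
    reduced representation bisulfite sequencing (RRBS) count data, modelled on
    the postnatal mouse liver. Provides a generative RRBS simulator (in-silico
    MspI digestion, size selection, cell-mixture and cell-division dilution,
    bisulfite non-conversion noise), readers and writers for Bismark coverage
    files and BED tracks, a quality-control cascade (coverage masking,
    missingness and never-methylated filters, sample-completeness scoring, CpH
    conversion screen), per-CpG two-group differential methylation with delta
    and FDR thresholds, time-course trajectory classification into discrete,
    continuous and other patterns, and CpG-density-matched resampling
    enrichment of genomic features.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.0),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    graphics,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
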