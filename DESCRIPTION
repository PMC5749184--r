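Package: scduoqc
Title: Quality Control and Integration Statistics for Paired Single-Cell DNA/RNA Sequencing
Version: 0.1.0
Authors@R:
    person("SIDR", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evaluation statistics for protocols that sequence the genome and
    transcriptome of the same single cell. Implements sequencing-quality
    summaries from alignment records, coverage-uniformity statistics for
    single-cell whole-genome amplification (bin-to-bin coefficient of
    variation, Lorenz curves with area-under-curve, per-chromosome power
    spectra), copy-number profiling by circular binary segmentation with
    permutation testing, single-cell RNA-seq quality metrics (gene detection,
    subsampling saturation, gene-body coverage, ERCC spike-in calibration,
    housekeeping-gene cell filters, cell-cycle staging), and genome-to-
    transcriptome integration (copy-number versus binned expression dosage
    correlation, bulk-explanation regression with adjusted R-squared, SNV
    concordance against bulk calls, cross-fraction contamination metrics,
    qPCR recovery arithmetic). A seed-reproducible synthetic-data generator
    emulates separated versus cross-contaminated preparations with known
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
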