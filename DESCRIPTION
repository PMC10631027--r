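Package: methyltrace
Title: Read-Level Detection of Tumor-Derived cfDNA from Whole-Genome
    Enzymatic Methyl-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for read-level detection of circulating
    tumor DNA (ctDNA) in cell-free DNA (cfDNA) methylomes. Calls
    differentially methylated CpG sites and regions (DMRs) between tumor and
    para-tumor tissue, denoises tumor-tissue reads with a Methylation
    Continuity Score (MCS) against healthy-cfDNA bounds, screens DMRs by a
    DMR Universality Score (DUS), recodes methylated CpGs for k-mer
    tokenization, pre-trains and fine-tunes a small bidirectional transformer
    encoder to classify reads as tumor-derived, aggregates per-read
    probabilities into an individual cancer risk score with four-fold
    threshold search, and supports ctDNA spike-in mixing simulations.
    Includes a fully synthetic methylome and read-set generator so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    jsonlite,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
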