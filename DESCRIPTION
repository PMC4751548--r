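Package: snparray
Title: Quality Control, Normalization and Genetic Analysis of SNP
    Genotyping Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for end-to-end handling of Illumina Infinium-style SNP
    genotyping array data: parsing BeadStudio/GenomeStudio FinalReport
    output, per-sample quality control and sex inference, thresholded
    quantile normalization (tQN) with computation of B-allele frequency
    (BAF) and log R ratio (LRR) against reference cluster positions,
    population-genetic summaries (allele frequencies, identity-by-state
    kinship, principal components, Mendelian-inconsistency checks),
    dataset merging with allele-encoding harmonization, a reference-panel
    haplotype-mosaic hidden Markov model, bit-exact PLINK binary export,
    and a synthetic-data generator so that every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    graphics,
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
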