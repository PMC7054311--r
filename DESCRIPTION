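Package: etohnet
Title: Ethanol-Dysregulated Transcription Factor Target Networks in the
    Early Zebrafish Embryo
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for pre-gastrulation ethanol-exposure
    transcriptomics in zebrafish: detection filtering and two-factor
    (treatment + batch) ANOVA on microarray signal matrices, Storey
    q-value false discovery rate control, signed fold-change selection of
    dysregulated genes, position-weight-matrix scanning of 2 kb upstream
    promoter windows with exact dynamic-programming p-values,
    hypergeometric enrichment of predicted transcription-factor targets
    in the dysregulated gene set, bipartite regulatory-network assembly,
    and comparative-CT (delta-delta-CT) qPCR quantification. Includes a
    synthetic-data generator that emulates the paired six-batch study
    design with planted fold changes and planted promoter motif sites, so
    every stage is testable against known ground truth without external
    downloads, and ships the published worked-example tables (GEO
    accession GSE145574) as machine-readable fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
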