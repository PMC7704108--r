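Package: memoryscan
Title: Identify Inflammatory Transcriptional-Memory Genes and
    Methylation-Encoded Memory Modules at NF-kB Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for studying TNF-alpha-induced
    transcriptional memory. Quantifies locus-specific DNA methylation from
    bisulfite Sanger clones, classifies TNF-alpha-responsive and
    transcriptional-memory genes from five-condition FPKM tables, and scores
    p65 (RELA) ChIP-seq peaks as candidate memory modules: kappaB-motif
    scanning, CpG accounting in motif flanks, total-methylation and
    demethylation scoring, peak state classification, peak-to-gene linking,
    lowess demethylation profiles, and methylation-aware signal
    normalization. Ships a deterministic synthetic-data generator emulating
    clone-level bisulfite patterns, methylation dynamics across genotypes,
    occupancy-methylation coupling, and planted memory-gene expression
    designs, so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    limma,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
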