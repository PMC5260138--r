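Package: methtable
Title: Gene-Level DNA Methylation Profiles from Whole-Genome Bisulfite
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reduces per-cytosine whole-genome bisulfite sequencing reports
    (BS-Seeker2 'CGmap' and Bismark cytosine reports) to gene-level DNA
    methylation profiles in the CG, CHG and CHH sequence contexts over
    promoters and gene bodies, written as a compact tab-delimited 'mtable'.
    Provides the downstream operations used in plant methylome studies:
    differentially methylated gene selection between dataset pools,
    methylation-threshold filtering, gene-list set algebra with Venn region
    decomposition, hypergeometric functional enrichment, and single-linkage
    hierarchical clustering for heatmap presentation. A bundled synthetic
    methylome simulator generates coherent annotation, ground truth and
    paired report files so the whole workflow runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    dplyr,
    generics,
    GenomeInfoDb,
    ggplot2,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
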