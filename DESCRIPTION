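Package: hmeripr
Title: Mapping and Interpreting 5-Hydroxymethylcytosine in mRNA from
    hMeRIP-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for hydroxymethylated RNA immunoprecipitation
    sequencing (hMeRIP-Seq). Calls 5hmC peaks from IP versus input
    fragment coverage over a transcriptome-restricted region with a local
    Poisson enrichment test and Benjamini-Hochberg correction, intersects
    peaks across replicates, quantifies per-condition IP/input RPKM
    enrichment ratios and calls differential marking by fold change,
    assigns peak summits to transcript structural elements, discovers
    center-enriched sequence motifs with a seeded ZOOPS-EM search against
    a first-order Markov background, calls protein-bound transcripts from
    RIP-Seq TPM tables, and relates 5hmC marking to transcript half-life,
    translation efficiency and intron retention. Ships a synthetic-data
    generator with planted ground truth so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
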