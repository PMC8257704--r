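Package: m6Amir
Title: Screening miRNA Seeds for m6A Consensus Motifs and Quantifying
    m6A-Dependent Target Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for analysing the interplay between
    N6-methyladenosine (m6A) mRNA modification and microRNA targeting.
    Screens a miRNA catalogue for seed regions whose reverse complement
    contains a degenerate m6A consensus motif (RRACH/GGACH), locates
    canonical seed-match target sites in 3'UTR sequences, classifies
    target genes by m6A status, compares RISC/AGO2 enrichment scores
    between m6A-modified and unmodified targets, and quantifies
    stage-wise down:up regulation ratios of target sets stratified by
    m6A status.  A synthetic-data module generates all pipeline inputs
    with planted ground truth so every stage is verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
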