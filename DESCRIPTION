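Package: tfrnet
Title: Signed Transcription-Factor Regulatory Network Inference from
    Binding Peak Sets and Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs stimulus-induced transcription factor regulatory
    networks from a pair of differentially expressed gene lists and a
    collection of TF binding peak sets (for example DAP-seq peaks). A
    three-step procedure tests each peak set for enrichment in the 1 kb
    promoters of up- and downregulated genes (one-sided Fisher exact test
    with Benjamini-Hochberg FDR control), classifies enriched TFs as
    stimulus-up- or downregulated activators or suppressors (DA, DS, US,
    UA), and infers signed regulator-to-target links restricted to the
    eight sign-consistent class pairs. The resulting graph is partitioned
    into a stimulus-repressed and a stimulus-activated subnetwork with a
    tier hierarchy on the DA-DA core. Includes promoter extraction with
    explicit strand conventions, gene-list overlay and promoter co-binding
    reports, a planted-network synthetic data generator for end-to-end
    validation, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
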