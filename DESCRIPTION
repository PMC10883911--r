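Package: cernakit
Title: Competing Endogenous RNA Network Inference from Transcript, Small RNA
    and Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for assembling sign-partitioned
    lncRNA-miRNA-mRNA competing endogenous RNA (ceRNA) networks from
    transcript annotation, sequence and count data, as used to profile
    osmotic-stress responses in fish kidney transcriptomes. Provides lncRNA
    candidate filtering, an ORF-length plus Fickett TESTCODE coding-potential
    heuristic, positional classification of lncRNAs against an mRNA
    annotation, small-RNA read collapsing and identity-based mature miRNA
    assignment, seed-weighted local complementarity alignment with a
    nearest-neighbor duplex energy model for miRNA target scanning, a
    negative-binomial Wald differential-expression engine with
    median-of-ratios normalization, Pearson co-expression filtering, and
    assembly, summary and Cytoscape export of up/down sign-partitioned ceRNA
    triplet networks. A synthetic-data generator with planted ground truth
    (binding sites, differential expression, sponge-consistent correlation)
    makes the whole chain testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
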