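Package: phagehic
Title: Phage-Host Linkage Inference from Hi-C Metagenomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for inferring phage-host infections from proximity-ligation
    (Hi-C) metagenome link tables. Implements multi-tool viral contig voting,
    greedy centroid vOTU clustering, CRISPR spacer-to-protospacer matching,
    coverage-based presence and abundance calling, a two-round link filtering
    procedure built on viral-copies-per-host (VPH) and connectivity-ratio
    estimators, infection network construction with replicate support,
    co-occurrence network inference (Pearson, CLR, random-forest importance)
    with centrality ranking, and pre/post treatment statistical comparisons.
    A fully specified synthetic soil-community simulator with recorded ground
    truth makes every stage testable without external sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
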