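Package: mircluster
Title: Evolutionary Analysis of microRNA Clusters from Small-RNA and
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-style toolkit for studying the birth, death and
    functional divergence of clustered microRNAs across species.  It
    validates miRNAs from hairpin read profiles using five expression
    criteria, dates member origination and loss on a species phylogeny by
    Dollo parsimony, classifies seed innovations (arm switching and seed
    shifting) and places them on branches by Fitch parsimony, predicts
    canonical seed-match targets (8mer/7mer) on expressed 3'UTRs,
    quantifies per-member and pooled-cluster target-set overlap across
    species through one-to-one ortholog maps, and tests target repression
    in control versus overexpression transcriptomes with two-sample
    Kolmogorov-Smirnov statistics.  A synthetic-data module generates
    inputs with the statistical structure the analysis assumes, so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    broom,
    jsonlite,
    knitr,
    phangorn,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
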