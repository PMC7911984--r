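Package: conscore
Title: Per-Base Genome Conservation Scores for Gene Drive Target Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects highly identical regions from pairwise whole-genome
    alignments with a sliding-window identity scan, combines them with
    phylogenetic distances, intraspecies SNP density and per-site selection
    scores into a per-base conservation score scaled to [0,1] per chromosome
    arm, and enumerates and ranks SpCas9 (NGG PAM) gene drive target sites by
    that score. Ships a synthetic-fixture generator (diverged genomes along a
    tree with embedded ultraconserved blocks, population SNPs, selection
    tracks and accessibility masks) so the whole pipeline is testable without
    external data. All user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stringr,
    tibble,
    tidyr,
    vcfR,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
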