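Package: karyoforge
Title: Ancestral Karyotype Reconstruction and Synteny Block Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects collinear gene blocks between chromosome-scale genomes in
    gene-rank space, reconstructs an ancestral karyotype by a two-round
    seed-and-extend procedure over multiple species, paints descendant genomes
    by their ancestral proto-chromosome of origin, and computes block-level
    statistics (collinearity degree, syntenic depth, arm-biased block
    distribution randomization test, transposable-element composition inside
    blocks versus gene-rank flanks). Ships a forward simulator of karyotype
    evolution (inversions, translocations, fissions, fusions, whole-genome
    duplication with fractionation, gene turnover, homology noise, and
    class-structured transposable-element landscapes) with a replayable event
    log and known truth painting, so recovery of the ancestor can be scored
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    stats,
    utils,
    generics,
    IRanges,
    mclust,
    rtracklayer,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
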