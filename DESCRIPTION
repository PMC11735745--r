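Package: popgenpanel
Title: Population-Genomic Analysis of Structured Genotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic analysis of multi-sample genotype
    panels: site-level filtering (k-mer mappability, coverage-mode
    accessibility, hard-filter expressions), KING-robust kinship and
    relatedness pruning, sliding-window LD pruning, individual
    heterozygosity and nucleotide diversity, a two-state HMM caller for
    runs of homozygosity, Hudson's FST with weighted block-jackknife
    standard errors, the X-to-autosome drift ratio (Q statistic),
    population-specific FST outliers, outgroup-polarized loss-of-function
    burden summaries, f3/f4 admixture statistics, genotype-distance
    matrices with neighbor-joining trees, and a structured-population
    genotype simulator with tree-shaped Balding-Nichols drift that
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    ape,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
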