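Package: introsel
Title: Diversity, Selection Scans and Introgression Mapping for SNP-Array Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end population-genomics toolkit for SNP-array genotype
    panels from livestock conservation programmes. Reads and writes PLINK
    bed/bim/fam and ped/map files and applies standard quality control;
    estimates heterozygosity, linkage-disequilibrium decay and effective
    population size (Sved equation); calls runs of homozygosity (ROH) with a
    PLINK-style sliding-window algorithm and derives F_ROH and SNP-based
    inbreeding coefficients; computes identity-by-state and Weir-Cockerham
    FST matrices, neighbor-joining trees, GRM-based principal components,
    supervised ancestry proportions, conservation-tier classification and
    NJ-tree family assignment; scans for selection with ROH incidence, the
    integrated haplotype score (iHS) and EigenGWAS; detects introgression
    with the f3 test, Patterson's D with block-jackknife errors, and
    windowed f_dM/dxy/pi statistics; and fits a single-SNP linear mixed
    model with a genomic relationship matrix. A forward Wright-Fisher
    simulator with recombination, an admixture pulse and exact local-ancestry
    bookkeeping provides ground-truth data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
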