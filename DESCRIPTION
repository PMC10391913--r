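Package: divscan
Title: Divergence Scanning, Phylogenetics and Mixed-Model Association for
    Two-Population Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for comparing two resequenced
    populations from a filtered SNP call set onward: site filtering on
    missingness and minor allele frequency, windowed nucleotide diversity
    and Weir-Cockerham FST with joint top-quantile sweep calling,
    allele-sharing distances with bootstrapped neighbor-joining trees,
    linkage-disequilibrium decay with a half-maximum linkage-distance
    summary, EMMAX-style mixed-linear-model association for continuous
    traits, and integration of sweep, association and differential
    expression evidence per gene. Ships a two-population Balding-Nichols
    simulator with planted sweeps, decaying linkage and causal phenotype
    architecture so every stage can be exercised against known ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
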