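Package: arraybias
Title: Simulating SNP Array Design and Ascertainment Bias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the design of a genome-wide SNP genotyping array and
    quantifies the ascertainment bias the design process introduces. Generates
    multi-population allele-frequency panels under a hierarchical
    Balding-Nichols model with a neutral-like site-frequency spectrum, runs the
    five-step array ascertainment procedure (discovery filtering, cluster
    removal, equal spacing on a genetic map with common-SNP backbones,
    validation, downsampling with exon retention), and measures how each step
    distorts derived allele-frequency spectra and expected-heterozygosity
    estimates across discovery, validation, application and outgroup
    populations, including mixed-model contrasts of the overestimation of
    heterozygosity between population groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
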