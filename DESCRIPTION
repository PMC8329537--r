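Package: recombinr
Title: Maternal Crossover Detection and Mixed-Model Analysis in Genotyped Cattle Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects maternal meiotic crossovers from three-generation
    families in a genotyped cattle pedigree (Mendelian trio phasing,
    informative-marker tracing, interval-resolved crossover calling with the
    standard density and quality filters), builds the covariates used to
    study recombination-rate plasticity (maternal age, birth year, and
    hot/cold temperature categories during two stages of fetal development),
    and fits a genomic mixed model (VanRaden genomic relationship matrix,
    exact REML) to estimate fixed effects and the heritability of the
    recombination rate. A synthetic-data module simulates pedigrees,
    genotypes, meioses, and farm temperature series with known truth so that
    every stage of the pipeline is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    grDevices,
    methods,
    tools,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
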