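Package: hsqtl
Title: Haplotype-Based QTL Mapping and Genetic Correlation in
    Heterogeneous Stock Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of multiparental mouse populations
    descended from eight inbred founder strains.  Provides a synthetic
    heterogeneous-stock (HS) genome simulator with known quantitative
    trait locus (QTL) architecture, founder-ancestry reconstruction by a
    hidden Markov model over founder-pair states, per-locus haplotype
    dosage regression (logP genome scans) with conditional mapping on
    covariate residuals, multilocus model selection summarised by
    resample model inclusion probabilities (RMIP) with positional 95%
    confidence intervals, genetic-correlation trees built from Sorensen
    similarity of QTL interval overlap, and a phenome-wide correlation
    screen with strain-panel replication.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
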