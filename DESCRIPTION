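Package: ssrcurate
Title: Curation of Multi-Allele SSR Fingerprint Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating microsatellite (SSR) fingerprint inventories of
    clonally propagated germplasm collections. Implements tolerance-aware
    Dice-Sorensen distances between multi-allele genotype profiles,
    distance-threshold clustering of replicate samples into molecular groups,
    cross-cohort allele-size harmonization, rule-based consensus genotype
    construction per cultivar, trueness-to-type aggregation, and reciprocal
    validation of consensus profiles against individual profiles. Ships a
    synthetic genebank generator with a complete injected-error ledger so the
    whole pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    purrr,
    Rcpp,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
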