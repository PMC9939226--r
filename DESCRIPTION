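Package: stratburden
Title: Location-Stratified Analysis of Tumor Response from Target-Lesion
    Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing solid-tumor treatment response from
    per-lesion CT measurements (longest and short axial diameters and
    volume). Computes RECIST 1.1-style per-patient tumor-burden changes,
    per-location stratified burden changes, and lesion-level independent
    changes; summarises response by treatment arm and anatomical location;
    fits a lesion-count-weighted mean response model per arm with a
    stratified permutation test for the inter-arm difference; decomposes
    response heterogeneity into location, patient and interaction shares
    via eta-squared; and runs outlier-exclusion and count-rebalancing
    sensitivity analyses. A synthetic two-arm multi-lesion trial generator
    with configurable location mixtures, effect sizes, patient random
    effects and dropout supports testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
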