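Package: mbvgrowth
Title: Genomic Adjustment of Net-Energy Growth Predictions for Feedlot Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates molecular breeding value (MBV) scores from commercial
    SNP panels and leptin genotypes into a net-energy growth model for feedlot
    cattle. Predicts the shrunk body weight at a target empty body fat (AFSBW)
    from hip height or carcass traits, projects days on feed and dry matter
    required, forms the difference variables that MBV scores can explain, fits
    and applies MBV-augmented adjustment equations (including stepwise
    selection), evaluates model adequacy (MSEP decomposition, concordance
    correlation, accuracy) with repeated random 2-fold cross-validation, and
    generates calibrated synthetic feedlot cohorts for testing the whole
    pipeline without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
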