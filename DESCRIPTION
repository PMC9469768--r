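Package: chlorosnap
Title: Automated Free-Chlorine Quantification from Test-Strip Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts a photograph of a DPD free-chlorine test strip on a
    standard background (black rectangle plus a QR-like fiducial) into a
    concentration estimate and a regulatory concentration tier. Implements
    two-stage white balancing (gray-world and white-patch reference), fiducial
    detection and perspective alignment, black-rectangle and strip
    localization, inscribed-circle pad color extraction, a family of
    RGB-to-concentration regression calibrations with backward stepwise AIC
    selection, binary and multiclass tier classification with the full
    precision/recall/F1 metric suite, stratified train-test splitting with
    resampled validation, and Bayes conditional misclassification
    probabilities. Ships a seeded synthetic scene renderer with full ground
    truth so every stage is testable without photographic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
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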