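Package: wearagree
Title: Thigh-Worn Accelerometer Posture Classification and Device Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies sitting, standing and stepping time from a thigh-worn
    triaxial accelerometer using a counter-based decision-rule state machine
    (normalized z-axis posture rule, three-mode step detector, weighted
    time-reconciliation against elapsed recording time), and validates such a
    monitor against a criterion posture device with the full method-comparison
    protocol: paired difference tests, Pearson/Spearman correlation, Lin's
    concordance correlation coefficient with McBride interpretation,
    Bland-Altman mean bias and limits of agreement, and TOST paired
    equivalence testing with escalating equivalence regions. Includes
    ground-truth-scripted synthetic signal and paired-measurement generators
    so the whole pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
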