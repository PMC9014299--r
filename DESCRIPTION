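Package: lcdiag
Title: Operating Characteristics of Binary Testing Methods Without a Gold
    Standard
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood estimation of the sensitivity, specificity
    and true-association prevalence of three or more conditionally
    independent binary testing methods applied to the same hypotheses,
    without any gold-standard reference (a Hui-Walter-type latent class
    model). Includes a nonparametric bootstrap for standard errors, a
    specificity-weighted association score combining the methods' calls,
    per-pair and overall posterior false discovery rates, p-value
    binarization with threshold sweeps for ROC-style evaluation, and a
    calibrated simulator for binary outcomes and p-value matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
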