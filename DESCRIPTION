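Package: skelegrow
Title: Skeletochronology Age, Growth, and Maturation Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating age, somatic growth, and maturation of
    long-lived reptiles from growth marks (lines of arrested growth, LAGs)
    measured in bone cross-sections. Implements the correction-factor
    approach for LAGs lost to bone resorption, body-proportional-hypothesis
    back-calculation of carapace length at every LAG, detection of sexual
    maturation from rapprochement (compression of outer LAGs), penalized
    spline size-at-age curves with individual random effects, and a
    bootstrapped Fabens von Bertalanffy growth model with age-at-size
    inversion. A synthetic bone-growth simulator with known ground truth
    supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    mgcv,
    generics,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
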