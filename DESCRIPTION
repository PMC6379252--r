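Package: grmdif
Title: Graded Response Model Calibration and Ordinal-Logistic DIF Screening
    for Polytomous Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Item-level psychometric analysis of short ordinal rating scales
    such as the 21-item Beck Depression Inventory-II. Calibrates Samejima's
    graded response model by marginal maximum likelihood (EM with fixed
    Gaussian quadrature), scores respondents by expected a posteriori (EAP)
    estimation, computes classical-test-theory descriptives (Cronbach's
    alpha, item-total statistics, cut-off classification), and screens items
    for differential item functioning (DIF) with the iterative hybrid
    ordinal-logistic-regression procedure: four nested proportional-odds
    models per item, likelihood-ratio tests, pseudo-R-squared change rules,
    uniform/non-uniform classification, and anchor purification. Includes a
    simulator for graded-response data with group structure and injectable
    DIF, and tabular item/test characteristic curves with ggplot2 displays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
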