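Package: tsdea
Title: Three-Stage Data Envelopment Analysis with Stochastic Frontier
    Input Adjustment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the operational efficiency of decision-making units
    with input-oriented data envelopment analysis (CCR and BCC envelopment
    programs), removes environmental and stochastic effects from the
    measured input slacks with per-input half-normal stochastic frontier
    regressions and the Jondrow-Lovell-Materov-Schmidt conditional
    inefficiency decomposition, and re-measures efficiency on the adjusted
    inputs (the Fried three-stage design). Includes a synthetic panel
    generator with recorded ground truth for validation, packaged fixtures
    of published province-level health-insurance efficiency tables, and
    tidy accessors for every intermediate result.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
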