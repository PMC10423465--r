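Package: biosavings
Title: Budget Impact of Biosimilar TNF Inhibitor Entry from Payer Reimbursement Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrospective budget-impact analysis of biosimilar entry for
    tumour necrosis factor inhibitors from annual public-payer reimbursement
    records. Implements two counterfactual savings models (estimated savings
    against pre-biosimilar reference prices and real-life savings against
    reference-year expenditure) with configurable reference-year rules and
    alternative scenarios, per-milligram and per-patient treatment-cost series
    with a two-method sensitivity check, defined daily dose (DDD) population
    exposure metrics, and a savings-reinvestment counterfactual that converts
    savings into potential additional treated patients. Ships the national
    Poland 2013-2021 infliximab/etanercept/adalimumab data set as a packaged
    fixture and a synthetic market-scenario generator with closed-form
    expected savings for validation.
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
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
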