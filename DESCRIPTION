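Package: standres
Title: Stand-Level Resilience of Managed Forests Under Stochastic Disturbance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo simulation framework for quantifying stand-level
    resilience of managed, even-aged forest stands. Simulates gap-cut and
    clear-cut silvicultural regimes under a stochastic, age-dependent
    disturbance regime with common random numbers across regimes, values the
    resulting provision streams for two ecosystem services (net revenues and
    aboveground carbon sequestration), estimates present values per stand
    state with a moving-window estimator, and derives recovery-time
    resilience gains, soil-expectation-value distributions and a trade-off
    metric relating performance losses to resilience gains. Survival, yield
    and valuation parameters are pluggable; shipped defaults are synthetic
    but structurally faithful so the full pipeline runs out of the box.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
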