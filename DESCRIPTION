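Package: floodbn
Title: Bayesian-Network Evaluation of Flood Interventions on Mental Health
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete Bayesian-network toolkit built around a health-economic
    case study: evaluating the mental-health benefit of flood interventions
    (such as early-warning systems) in QALY and monetary terms. Provides exact
    inference by variable elimination, conditional-probability-table learning
    with Dirichlet smoothing, BIC-scored hill-climbing structure search,
    labeled-DAG counting, ancestral (forward) sampling of synthetic survey
    records, a packaged flood/depression network calibrated to elicited
    marginal probabilities, change-in-QALY cost-effectiveness evaluation at a
    willingness-to-pay threshold, and probabilistic sensitivity analysis over
    Beta-distributed health-state utilities with a Monte-Carlo EVPI estimator.
    All results are returned as tibbles with broom-style tidiers and ggplot2
    autoplot methods.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
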