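Package: pluralvote
Title: Plurality-Vote Reliability Analysis for LLM Sentiment Annotation
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how reliably a large language model
    reproduces human sentiment labels when each message is classified
    repeatedly and the machine decision is taken as the plurality of m
    response instances resampled with replacement from a pool of N
    independent responses. Provides Monte Carlo and exact-enumeration
    estimates of per-message concurrence accuracy, category-level K_m
    summaries with standard errors, misclassification flow tables,
    Mann-Whitney rank comparisons between categories, and a calibrated
    Dirichlet-multinomial generator of synthetic response pools so the
    whole pipeline is testable without any API call.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
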