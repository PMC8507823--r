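Package: teenits
Title: Interrupted Time Series Analysis of Social Media Engagement and
    Emotion in Teen Communities
Version: 0.1.0
Authors@R: person("teenits", "maintainers", email = "teenits@example.org",
    role = c("aut", "cre"))
Description: Tools to study weekly posting behaviour and lexicon-based
    emotion expression of online teen communities around an interruption
    such as the COVID-19 pandemic declaration. Provides a synthetic
    Reddit-like corpus generator with planted cohort structure and
    segmented posting dynamics, five-emotion dictionary scoring with a
    compound negative-emotion scale, weekly engagement aggregation over
    username-matched cohorts, and a two-group interrupted time series
    model (segmented OLS with Newey-West autocorrelation-adjusted
    standard errors and a residual-autocorrelation lag diagnostic).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
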