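Package: facexpr
Title: Quantitative Assessment of Facial Expression Production from Action
    Unit Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores how well a subject produces the four basic facial
    expressions (happiness, sadness, fear, anger) from per-frame facial
    Action Unit (AU) intensity time series, as used in behavioral-imaging
    protocols for children with autism spectrum disorder. Implements
    head-pose reliability gating, adaptive-degree polynomial smoothing,
    co-occurrence based regularization of AU intensities, a personalized
    short-term Gaussian-mixture baseline of the non-emotional face with
    negative log-likelihood variation scoring, per-expression upper and
    lower face production scores with ability classification, and a
    synthetic session simulator with ground truth for end-to-end
    validation.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
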