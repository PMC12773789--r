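Package: hardshipdyn
Title: Economic Unpredictability Statistics for Longitudinal Hardship Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies environmental unpredictability in repeated subjective
    economic-hardship reports. Turns long-format monthly survey responses into
    per-family time series, computes four unpredictability indices (coefficient
    of variation, penalized changepoint counts in mean and in variance, and
    1/f spectral noise color), reduces them to a variance-explained-weighted
    principal-component composite, and estimates effects of hardship severity
    and unpredictability on a child self-regulation outcome using balancing
    weights for continuous exposures (generalized-propensity-score density
    ratios and entropy balancing) with weighted regression and robust standard
    errors. Includes a synthetic cohort generator with planted ground truth so
    every stage is testable without access to restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    sandwich
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
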