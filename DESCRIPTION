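Package: simcost
Title: Self-Injury Mortality Measurement and Societal Cost Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for operationalizing self-injury mortality (SIM) -- a
    composite of suicides and the preponderance of accidental and
    undetermined-intent drug intoxication deaths -- from aggregated
    underlying-cause-of-death data, and for estimating its societal cost.
    The cost engine assigns medical spending by place of death, values lost
    work (wages, fringe benefits and household work) as a survival-weighted
    discounted stream over the remaining life span, and monetizes lost
    quality of life from a value per statistical life net of lifetime work
    loss.  Includes parsers for WONDER-style tab-delimited mortality
    exports, state/national reporting surfaces (per-capita costs, period
    percent changes, rankings, quintiles, Bureau of Economic Analysis
    regions), published reference tables as machine-readable fixtures, and
    a synthetic-data generator with analytic ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
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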