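Package: leadtto
Title: Lead-Time Time Trade-Off Valuation of EQ-5D-5L Health States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing lead-time time
    trade-off (TTO) valuation studies of EQ-5D-5L health states in the style of
    the EuroQol valuation technology (EQ-VT). Provides the deterministic value
    algebra U = (T - LT)/UT, an iterative elicitation engine that reproduces the
    EQ-VT offer sequence with censoring at the bounds of the tradable-time grid,
    a synthetic-respondent simulator with decision noise, indifference tolerance
    and lead-time framing, visual-contrast and engagement bias mechanisms, the
    standard data-cleaning rules for valuation records, and the arm-comparison
    analyses used in valuation pilot studies: per-state and grand summaries,
    aggregate cross-arm regression, seven-bin response-behaviour tables and
    covariate-adjusted mixed-effects comparisons with respondent-level
    clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    lme4,
    lmerTest,
    sandwich,
    lmtest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
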