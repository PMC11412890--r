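Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for pharmacovigilance signal detection
    on FAERS-style spontaneous adverse event reports. Reads quarterly
    "$"-delimited ASCII tables, deduplicates case versions, selects reports by
    primary-suspect drug, builds drug-event 2x2 contingency tables at the
    MedDRA preferred-term or system-organ-class level, and computes five
    disproportionality statistics: the reporting odds ratio, the proportional
    reporting ratio, the MHRA chi-square composite, the Bayesian confidence
    propagation neural network information component, and the multi-item gamma
    Poisson shrinker with an empirically fitted two-component gamma prior.
    Includes per-algorithm signal screening with important-medical-event
    flagging and overlap summaries, information-component time trends,
    descriptive report summaries, and a synthetic report generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
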