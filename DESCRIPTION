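Package: crvalidate
Title: External Validation of Time-to-Event Risk Models with Competing Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for externally validating time-to-event risk prediction
    models in settings where competing events occur. Implements calibration
    measures (observed/expected ratios, grouped calibration, pseudo-value
    smoothed calibration curves) based on the Aalen-Johansen cumulative
    incidence function, alongside the naive censor-competing-events versions
    so the two can be contrasted. Discrimination measures include Harrell's
    C-index, Wolbers' competing-risk adaptations, a truncated IPCW C-index,
    and the Royston-Sauerbrei D statistic (with explained variation R2_D)
    computed from self-contained single-covariate Cox and Fine-Gray fitters.
    Seeded simulators of competing-risk cohorts with known truth make every
    measure testable without access to registry data.
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
    KernSmooth,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    cmprsk,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
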