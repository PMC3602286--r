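Package: cesdmi
Title: Missing-Data Strategies for the CES-D Depression Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scoring, classification and missing-data handling for the 20-item
    Center for Epidemiologic Studies Depression (CES-D) scale. Provides
    bound-based classification of partially observed responders, deterministic
    single-imputation comparators (minimum, maximum, person-mean), a multiple
    imputation engine using chained equations with predictive mean matching,
    polytomous and logistic regression methods, Rubin's rules pooling, an
    MCAR amputation study for benchmarking imputation accuracy, a
    pattern-mixture (odds-ratio / delta shift) sensitivity analysis for
    nonignorable missingness, psychometric summaries (Cronbach's alpha,
    principal-component spectrum), and a calibrated generator of synthetic
    cohorts with a unidimensional 20-item ordinal scale, a depression
    risk-factor covariate block and configurable MCAR/MAR/MNAR missingness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
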