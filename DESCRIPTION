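Package: oculoseq
Title: Prestimulus Oculomotor Inhibition and Foreperiod Sequential Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for prestimulus oculomotor inhibition in
    foreperiod (temporal-expectation) paradigms. Simulates binocular gaze
    recordings with planted microsaccades, blinks and a known logistic model
    of pretarget saccade probability; detects saccades with a binocular
    velocity-threshold algorithm with main-sequence quality control; builds
    trial-level tables with foreperiod-difference covariates and exclusion
    rules; and fits binomial-logit mixed models with a parsimonious
    random-effects ladder, Type-II likelihood-ratio tests, BIC-approximated
    Bayes factors and FDR-corrected contrast tables. Includes
    within-subject-corrected summaries and figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    MASS,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    withr
Config/testthat/edition: 3
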