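Package: maternalcv
Title: Cross-Validated All-Subsets Model Selection for Multi-Country
    Maternal Mental Health Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying risk and protective factors for maternal
    mental health across country cohorts with repeated k-fold
    cross-validation. Provides a seeded synthetic cohort generator that
    emulates the psychometric structure of multi-country lockdown surveys
    (Likert item scales with target reliabilities, correlated symptom
    subscales, country-specific prevalences and effects), composite scale
    scoring with Cronbach's alpha, an exhaustive best-subset linear
    regression search ranked by cross-validated root mean square error of
    prediction with winner-frequency tallies, cross-country transfer
    validation of selected models, robust (HC3) standardized refits, and
    moderation analysis with simple slopes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    sandwich,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
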