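Package: pubsync
Title: Integrated Physical and Hormonal Profiling of Early Pubertal Maturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying pubertal maturation in large pediatric cohorts
    of 9-10 year olds. Scores the Pubertal Development Scale (average, gonadal,
    adrenal and category scores with the standard missing-data rules), applies a
    decision-tree quality control to duplicate salivary hormone immunoassays
    (DHEA, testosterone, estradiol), computes LMS growth-reference BMI z-scores
    and weight status, quantifies caregiver-youth agreement with weighted
    Cohen's kappa and polychoric correlations implemented from first principles,
    and integrates perceived physical features with hormone levels through a
    Bayesian group factor analysis with automatic-relevance-determination
    sparsity fit by Gibbs sampling. Includes replication, split-half and
    covariate-extension stability procedures, latent synchrony profiling, and a
    synthetic cohort generator so the whole pipeline is testable without
    access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    withr,
    knitr
Config/testthat/edition: 3
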