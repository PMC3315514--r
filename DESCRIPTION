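Package: coref
Title: Coreferentiality Testing Against Multivariate Reference Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether two variables of interest parallel each other in
    their correlations with a shared multivariate reference data set
    ("coreferentiality"). Provides the coefficient of coreferentiality (the
    Pearson correlation of the two correlation profiles), a permutation
    significance test with joint reshuffling of the test variables, a
    bystander-control diagnostic, a synthetic-data generator with
    gradient-weighted linear mixtures, and Monte-Carlo power-study tooling
    including PCA-regression and bivariate-regression baselines.
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
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
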