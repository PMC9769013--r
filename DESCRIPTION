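Package: housemort
Title: Small-Area Housing Deprivation Indices and Mortality Inequality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds small-area housing deprivation indices from individual
    housing records (household and profile-based imputation, sector
    prevalences, maximum-likelihood factor analysis, decile ranking) and
    quantifies mortality inequality across deprivation deciles: direct age-
    and sex-standardized mortality rates, adjusted Lorenz curves and Gini
    coefficients, population attributable fractions and excess deaths with
    Monte Carlo confidence intervals, abridged period life tables, Arriaga
    decomposition of life-expectancy gaps, and potential years of life lost.
    Includes a synthetic population-register generator with known
    deprivation gradients for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
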