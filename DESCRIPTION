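Package: pgxscreen
Title: Knowledge-Based Two-Stage SNP Screening and Integrated Allele-Count
    Indices for Pharmacogenomic Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for small-cohort pharmacogenomic association screening:
    knowledge-based SNP prefiltering, allele/dominant/recessive contingency
    analysis with exact tests, two-stage screening across nested patient
    datasets with min-statistic permutation family-wise error control,
    logistic and proportional-odds model comparison by AIC and ROC, an
    integrated minor-allele-count predictive index, and inverse
    reconstruction of integer contingency tables from published rounded
    statistics. Includes a study-shaped synthetic data generator so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
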