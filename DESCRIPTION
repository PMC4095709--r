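Package: mixdiff
Title: Ensemble Mixture Models for Differential Analysis of
    High-Throughput Genomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Differential analysis of per-unit difference scores
    (log-ratios of expression, methylation, or protein-binding signal
    between two conditions) with an ensemble of three finite mixture
    model classes: uniform plus one normal (NUDGE), uniform plus K
    normals (iNUDGE), and two shifted exponentials plus K normals (GNG).
    Models are fitted by a robust weighted-likelihood EM algorithm with
    lower-half Huber (or Tukey) intensity weights, the number of normal
    components is chosen by BIC within each class and the winning class
    by AIC, normal components are labelled differential by an
    interquartile-range outlier rule, and units are called differential
    by a weighted local false discovery rate threshold. A built-in
    simulator generates two-condition datasets with known differential
    labels for power and type-I-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
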