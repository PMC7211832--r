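Package: roostnet
Title: Social Structure Analysis of Roost-Capture Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring social structure from roost-capture records of
    individually marked bats (or other fission-fusion group-living animals).
    Builds group-by-individual matrices and simple-ratio association indices,
    quantifies social differentiation as the coefficient of variation of the
    index, tests for preferred associations with constrained datastream
    (pre-network) permutations that hold population, roost and year fixed,
    tests kin-biased association with Mantel and quadratic-assignment (QAP)
    matrix regressions against either node-permutation or pre-network nulls,
    and runs permutation tests of sex-biased roost use and philopatry. A
    pedigree-based colony simulator generates capture datasets and relatedness
    matrices with known ground truth for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
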