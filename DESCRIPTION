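Package: lderge
Title: Gene-Environment Interaction Variance from Summary Statistics with Full LD Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the proportion of phenotypic variance explained by
    genome-wide gene-environment (GE) interactions from genome-wide
    interaction scan (GWIS) summary statistics. Implements LDER-GE, a
    method-of-moments estimator that eigen-decomposes block-wise linkage
    disequilibrium (LD) matrices and regresses transformed squared
    interaction Z-scores on eigenvalues with iterative weighted least
    squares, exploiting the full LD matrix rather than only the diagonal
    of its square as LD-score-based baselines do. Includes an LDSC-style
    diagonal baseline, delete-block jackknife standard errors, liability
    scale transforms for binary traits, aggregation of multi-covariate
    interaction variance via sequential residualization, reference-panel
    construction with linear shrinkage, and a simulation engine with
    block-correlated genotypes and a direct moment-model summary-statistic
    sampler for calibration studies.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
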