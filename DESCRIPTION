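Package: magrs
Title: Minor-Allele Burden and Weighted Genetic Risk Scores for
    Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the genome-wide accumulation of minor
    alleles in case-control SNP cohorts and for building risk-prediction
    models from it.  Implements genotype input/output (PLINK bed/bim/fam
    and a plain-text dialect), Hardy-Weinberg/missingness/frequency
    quality control, minor-allele assignment from controls, per-subject
    minor-allele content (MAC), windowed pairwise-r2 LD pruning, per-SNP
    logistic association, weighted genetic risk scores (wGRS) and
    polygenic risk scores (PRS), discrimination metrics (AUC with DeLong
    intervals, true-positive rate at 100% specificity, Nagelkerke
    variance explained), grids of prediction models evaluated by
    external and internal cross-validation, and a liability-threshold
    case-control cohort simulator with blockwise linkage disequilibrium.
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
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
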