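Package: crosstrait
Title: Cross-Trait Genetic Comorbidity Analysis from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the molecular genetic relationship between two
    complex traits using only genome-wide association study (GWAS) summary
    statistics. Implements summary-statistics harmonization and p-value
    informed LD clumping; SNP effect concordance analysis (SECA) with Fisher
    exact tests over a 12x12 p-value subset grid and permutation inference;
    LD score regression for SNP heritability (with liability-scale
    conversion) and cross-trait genetic correlation with block-jackknife
    standard errors; fixed-effect and Han-Eskin RE2 cross-disorder
    meta-analysis; two-sample Mendelian randomization (IVW, MR-Egger,
    weighted median, mode estimators, heterogeneity and leave-one-out
    diagnostics); gene-based Best-SNP association tests with effective
    independent gene counts, Fisher combined p-values and exact binomial
    overlap tests; and gene-set over-representation analysis. A seeded
    synthetic-data generator with known ground truth makes every stage
    testable without consortium data.
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
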