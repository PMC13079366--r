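Package: genlottery
Title: Genetically Informed Estimation of the Returns to Schooling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates pedigree-linked cohorts with Mendelian transmission at
    independent trait-associated SNPs, a weighted polygenic index, integer years
    of schooling and age-indexed earnings panels, together with the confounding
    channels (individual ability, genetic nurture, assortative mating,
    population stratification, pleiotropy) that threaten genetically informed
    causal inference. Provides the full estimator suite for
    Mendelian-randomization studies of the returns to schooling: OLS, sibling
    and twin fixed effects, two-stage least squares with a polygenic
    instrument, sibling-MR, Anderson-Rubin confidence intervals,
    cluster-robust inference, covariate balance diagnostics, summary-level MR
    (IVW, Egger, weighted median, mode, core-gene ranking, leave-one-out),
    within-sibling family-based GWAS instruments, union-of-confidence-interval
    sensitivity analysis for exclusion violations, an IV-OLS gap decomposition
    with margin and covariate weights, and life-cycle returns with internal
    rates of return.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
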