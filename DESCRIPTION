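Package: pgsproteome
Title: Polygenic Scores, the Circulating Proteome, and Cardiometabolic Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline linking polygenic scores for type 2
    diabetes and cardiometabolic comorbidities to circulating protein levels
    and clinical outcomes. Implements two-stage polygenic-score/protein
    association scanning with Bonferroni discovery and per-score FDR
    replication, natural-effects causal mediation with confounding
    sensitivity analysis, two-sample / multivariable / reverse Mendelian
    randomisation with instrument quality control and a median-p consensus
    rule, approximate-Bayes-factor colocalization, tiered Cox
    proportional-hazards trial endpoint analysis, and background-restricted
    pathway over-representation. A synthetic-cohort generator with a
    recorded ground truth emulates the statistical structure every stage
    assumes (cis/trans pQTL architecture, adiposity-mediated chains,
    non-overlapping GWAS samples, shared/distinct causal variants, censored
    trial survival) so the whole framework is exercised end-to-end against
    known effects.
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
    survival,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
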