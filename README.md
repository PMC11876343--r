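# pgsproteome

Polygenic scores (PGS) summarise a person's germline liability to a
disease as a weighted sum of allele dosages. When a cardiometabolic PGS
associates with the level of a circulating protein, that association can
arise several ways — the protein may sit on the causal path to disease,
the association may be mediated by adiposity, or the developing disease
itself may alter the protein (reverse causation). Telling these apart is
what decides whether a protein is a drug target, a biomarker, or a
bystander.

`pgsproteome` implements the full analytic chain for this question as a
tidyverse-style R package — every user-facing function takes a data
frame and returns a tibble — aimed at statistical geneticists and
biomarker analysts:

* **Scoring** — PGS from PGS-Catalog-style weight files
  (`compute_pgs()`, allele-flip aware), plus greedy LD clumping
  (`clump()`: smallest p first, r² < 0.1, 250 kb window) to derive
  GWAS-significant weight sets.
* **Association scan** — `run_scan()`: per-SD linear associations of
  every score with every protein, Bonferroni discovery at
  `alpha / (scores x proteins)` (1.7e-6 at the 10 x 2922 study scale)
  and within-score Benjamini-Hochberg replication; `adjusted_scan()`
  classifies pairs as attenuated or robust under BMI / waist / pQTL
  adjustment.
* **Mediation** — `mediate_continuous()` (product of coefficients,
  `nie = a·b`, `nde = c'`) and `mediate_binary()` (imputation-based
  natural effects on the log-odds scale), bootstrap inference,
  `sensitivity_rho()` for mediator-outcome confounding.
* **Mendelian randomisation** — `harmonize()`, `instrument_qc()`
  (F ≥ 10, pQTLs hitting ≥ 5 proteins removed, ≥ 3 cis instruments),
  the four conventional estimators (`ivw()`, `median_mr()`, `egger()`),
  a median-p `consensus()` with the Egger-intercept pleiotropy gate,
  multivariable MR (`mvmr()`, conditional F and pleiotropy Q gates), and
  `reverse_mr()` with 500 kb / 5e-8 / r² < 0.001 instrument selection.
* **Colocalization** — `coloc()`: Wakefield approximate Bayes factors,
  priors p1 = p2 = 1e-4, p12 = 1e-5, and the decision rule
  PP.H3 + PP.H4 > 0.99 with PP.H4/PP.H3 > 5.
* **Trial survival** — `endpoint_scan()`: tiered Cox models
  (base / clinical / + NT-proBNP) on MACE, heart-failure and renal
  endpoints via `survival::coxph`, proportional-hazards flags
  (`ph_test()`), repeat-measurement diagnostics, and PGS-to-event
  mediation.
* **Enrichment** — `enrich()`: background-restricted hypergeometric
  over-representation with BH FDR.
* **Synthetic cohorts** — `sim_config()` / `simulate_genotypes()` /
  `simulate_cohort()` / `simulate_trial()` generate genotypes with AR(1)
  LD, a PGS → BMI → protein → disease mediation chain with a tunable
  mediated fraction, shared/distinct colocalization scenarios,
  reverse-causation proteins, and censored trial outcomes — with every
  true effect recorded in a truth ledger, so the whole pipeline is
  testable against known answers. `run_pipeline()` chains all nine
  stages deterministically under one seed.

## Worked example

Simulate a cohort with 5 PGS-target proteins among 20, score it with the
generator's own weights, and run the two-stage scan:

```r
library(pgsproteome)

cfg  <- sim_config(n_proteins = 20, n_pgs_targets = 5,
                   n_causal_proteins = 5, n_coloc_distinct = 2, seed = 7)
geno <- simulate_genotypes(cfg)
sim  <- simulate_cohort(cfg, geno)
cohort <- filter_prevalent(sim$cohort)

scores <- compute_pgs(geno, truth_weightset(sim$truth, "pgs_t2d"),
                      reference = which(sim$cohort$stratum == "discovery"))
scan <- run_scan(cohort, tibble::tibble(sample_id = scores$sample_id,
                                        pgs_t2d = scores$score_std))
glance(scan)
#> # A tibble: 1 × 5
#>   n_scores n_proteins bonferroni_threshold n_discovery_significant n_replicated
#>      <int>      <int>                <dbl>                   <int>        <int>
#> 1        1         20               0.0025                       5            5
```

All five planted targets replicate and nothing else does. The strongest
replicated pairs, with per-SD betas and partial R²:

```r
head(dplyr::arrange(scan$replication, qval), 3)
#>   score_id protein_id  beta     se t_stat     pval r2_partial     n     qval
#> 1 pgs_t2d  protein_05 0.183 0.0227   8.10 9.78e-16     0.0335  1906 4.89e-15
#> 2 pgs_t2d  protein_04 0.178 0.0226   7.88 5.41e-15     0.0318  1906 1.35e-14
#> 3 pgs_t2d  protein_02 0.142 0.0227   6.25 5.07e-10     0.0202  1906 8.45e-10
```

Two-sample MR for one disease-causal protein, using its cis pQTLs from
the exposure stratum against the disease GWAS from the non-overlapping
outcome stratum:

```r
iexp <- which(sim$cohort$stratum == "gwas_exposure")
iout <- which(sim$cohort$stratum == "gwas_outcome")
pqtl    <- protein_gwas(subset_samples(geno, iexp), sim$cohort[iexp, ],
                        "protein_08", cohort_covariates(sim$cohort[iexp, ]))
disease <- compute_summary_stats(subset_samples(geno, iout),
                                 sim$cohort$incident_disease[iout],
                                 cohort_covariates(sim$cohort[iout, ]), "cc")
mr <- mr_scan(pqtl, disease, geno,
              annotation = instrument_annotation(sim$truth, geno),
              n_boot = 500, seed = 7)
mr$consensus
#>   protein_id  median_p pleiotropy_flag ivw_estimate ivw_se n_instruments
#> 1 protein_08   5.90e-7 FALSE                  0.488 0.0813             5
```

`protein_08` is one of the planted causal proteins: five cis instruments
survive QC, the consensus (median of the four method p-values) is
significant, and the IVW log odds per SD (0.49) recovers the planted
liability effect after the usual logistic attenuation. Mediation of a
target protein's PGS association through BMI:

```r
disc <- dplyr::mutate(sim$cohort[sim$cohort$stratum == "discovery", ],
                      pgs = scale(pgs_true)[, 1])
med <- mediate_continuous(disc, "pgs", "bmi", "protein_01",
                          covariates = cohort_covariates(disc),
                          n_boot = 500, seed = 7)
tidy(med)
#>   effect   estimate ci_low ci_high    pval
#> 1 direct     0.133  0.100   0.168  0.00399
#> 2 indirect   0.0298 0.0200  0.0404 0.00399
#> 3 total      0.163  0.129   0.196  0.00399
```

The indirect (BMI-mediated) share of the total effect is 0.18 here; the
generator's truth for this protein is 0.25, within sampling error at
n = 4000. `run_pipeline(sim_config(seed = 1))` chains simulation,
scoring, scanning, mediation, MR (forward, multivariable, reverse),
colocalization, trial survival, and enrichment, returning a manifest of
stage statuses, row counts and file digests.

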