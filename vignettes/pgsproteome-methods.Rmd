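---
title: "Methods: linking polygenic scores to the circulating proteome and clinical outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking polygenic scores to the circulating proteome and clinical outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgsproteome)
```

# What the package does

`pgsproteome` implements, as one tested pipeline, the chain of analyses
used to connect polygenic scores (PGS) for type 2 diabetes and its
cardiometabolic comorbidities to circulating protein levels and to
clinical outcomes:

1. polygenic scoring from weight files, including clump-derived
   GWAS-significant weight sets;
2. a two-stage PGS-protein association scan (Bonferroni discovery,
   per-score FDR replication) with adiposity and pQTL adjustments;
3. natural-effects causal mediation (PGS -> BMI -> protein;
   PGS -> protein -> incident disease; PGS -> protein -> trial event);
4. two-sample, multivariable, and reverse Mendelian randomisation (MR)
   with instrument QC and a median-p consensus rule;
5. approximate-Bayes-factor colocalization;
6. tiered Cox proportional-hazards analysis of trial endpoints with
   repeat-measurement diagnostics;
7. background-restricted pathway over-representation.

Because the data these methods were designed for (biobank proteomics and
trial biomarker panels) are not redistributable, the package ships a
synthetic-cohort generator whose draws have a recorded ground truth (the
*truth ledger*). Every downstream method is exercised against planted
effects, so the test suite measures calibration, parameter recovery, and
scenario discrimination rather than agreement with any private dataset.

# The synthetic cohort

## Genotypes and linkage disequilibrium

Each protein owns a cis region of `n_variants_per_cis_region` variants on
its own chromosome; polygenic-score variants sit on a separate chromosome
far enough apart to be independent. Within a region, haplotypes follow a
first-order Markov chain on allele state: one minor-allele frequency
(MAF) per region drawn from `maf_range`, and each allele copies its left
neighbour with probability `ld_rho`. This gives marginal frequency MAF at
every variant and dosage correlation exactly `ld_rho^d` at distance `d` —
an AR(1) LD profile. A latent-Gaussian threshold model was rejected
because thresholding attenuates the allelic correlation below the nominal
parameter, which would make the LD knob misleading for clumping and
colocalization tests. The price of the Markov construction is a constant
MAF within each region; across regions MAFs vary freely.

## Phenotypes and the mediation chain

With the standardized true score `PGS`:

* `BMI = gamma * PGS + small covariate terms + noise` (`gamma = 0.3` per
  SD by default);
* every protein receives cis effects scaled to a cis heritability of
  `protein_h2_cis` (0.2 by default, spread over `n_causal_cis = 5`
  variants placed far enough apart to survive clumping at r² < 0.1,
  with geometrically decaying variance shares — equal shares would give
  every instrument the same effect magnitude, leaving MR-Egger's
  slope/intercept split unidentified);
* *target* proteins additionally receive
  `delta * PGS + b * BMI`, with `delta = (1 - f) * tau` and
  `b = f * tau / gamma` so the total PGS effect is `tau`
  (`pgs_protein_total = 0.15`) and the mediated proportion
  `gamma * b / (gamma * b + delta)` equals `mediated_fraction` exactly;
* residual noise tops every protein's variance up to 1, and a
  configuration whose components exceed 1 is rejected.

Incident disease is a logistic liability in the causal proteins
(`protein_disease_logodds` each), BMI, a direct polygenic term, planted
colocalization variants, and covariates; the intercept is calibrated by
root finding so the incident fraction matches `disease_prevalence`.
Prevalent disease is an independent baseline flag (association analyses
exclude it, mirroring a baseline-diagnosis exclusion), and
`incident = 1` forces `prevalent = 0`.

## Effect sizes as scaled-down study conditions

The desk-scale default (4000 discovery / 2000 replication samples, a
10,000-sample binary outcome GWAS, 50 proteins) is orders of magnitude
smaller than the cohorts the methods were built for. So that the tests
measure the *methods* rather than raw sample size, generator effect sizes
compensate by design, fixed from power calculations before any test was
run:

* a cis instrument carries a per-variant disease z-score of roughly
  `theta * sqrt(h2_cis / k * n * prev * (1 - prev))`; at `n = 10^4`,
  `h2_cis = 0.2` over `k = 5` variants and 10% prevalence this is about
  `6 * theta` after liability attenuation, so the causal log odds per SD
  is set to `theta = 0.8` to give per-instrument z around 4 and an IVW
  z around 9 — comfortably detectable, as a 400k-sample GWAS would make
  a much smaller effect;
* a *polygenic* binary trait has no genome-wide-significant variants at
  `n = 10^4`, so the default pipeline honestly records the reverse-MR
  stage as a no-instrument skip. The direction-of-causation analyses use
  a sparse architecture instead (12 trait variants carrying
  `disease_pgs_logodds = 1.2` per SD), for which each variant's expected
  disease z is about `1.2 / sqrt(12) * sqrt(n * 2f(1-f) * prev(1-prev))
  ≈ 6`, clearing the 5e-8 instrument threshold.

## Trial survival data

`simulate_trial()` draws, per endpoint (MACE, heart-failure
hospitalisation, renal), exponential event times with log-hazard
`trial_log_hr` per SD of each trial-causal protein plus age/sex and
clinical risk-factor terms, independent exponential censoring at
`censor_rate`, and an administrative end at `trial_followup` years. Both
arms are generated (the arm has no effect; analyses restrict to placebo,
with the arm as a covariate in mediation). Two protein timepoints have
test-retest correlation `test_retest_r`. Two scenario switches support
the diagnostics:

* `reverse_causation = TRUE` re-expresses the two timepoints of causal
  proteins as noisy measurements of the hazard-driving level and adds an
  early-disease term (`event * exp(-time / followup)`) to the repeat
  only, so repeat-based hazard ratios inflate relative to baseline and
  adjusting for the baseline measurement ameliorates part of the
  inflation;
* `confounded_protein = TRUE` redefines the last protein as an eGFR
  proxy with no hazard of its own, so its association survives the base
  covariate tier but not the clinical tier.

# Analytic components

## Scoring and clumping

Scores are `sum_j w_j d_ij` with dosages flipped to `2 - d` when the
weight's effect allele is the matrix's other allele. Weight variants
absent from the matrix are dropped by default; the `mean_impute` policy
substitutes `2 * eaf` from an allele-frequency column in the weight file
(the matrix itself cannot supply a frequency for a variant it does not
contain), and in-matrix `NA` dosages are column-mean imputed. Clumping is
the greedy index-variant rule (smallest p first, neighbours within the
window claimed at r² above threshold); ties on p are broken by
lexicographic variant id so output is independent of row order. Defaults
are p < 5e-8, r² < 0.1, 250 kb; reverse-MR instrument selection uses
p < 5e-8, r² < 0.001, 500 kb.

## The association scan

Proteins and scores are standardized before regression, so betas are per
SD on both sides and cross-score beta comparisons are scale-free.
Discovery significance is Bonferroni at `alpha / (scores x proteins)` —
at the full study scale of 10 scores and 2922 proteins, 1.7e-6 —
and replication applies Benjamini-Hochberg within each score, never
pooled, with q < 0.05. Variance explained is the partial R² of the score
term, `t² / (t² + df)`, not model R². Models significant *only after* an
adjustment are flagged and excluded from headline counts, because
conditioning on a downstream variable (BMI, a pQTL genotype) can induce
collider bias. Missing protein values are complete-case per protein; all
tests are two-sided.

## Mediation

Continuous mediation is the product-of-coefficients decomposition
(`nie = a*b`, `nde = c'`, additive by construction); binary-outcome
mediation uses the imputation-based natural-effects approach: a logistic
imputation model, row duplication with a permuted counterfactual
direct-path exposure, and a natural-effects logistic fit whose two
exposure coefficients are the direct and indirect log odds ratios.
Inference is a row-resampling percentile bootstrap throughout (default
1000 replicates, seeded, refusing below 100) rather than the delta
method: it is assumption-light, matches the resampling spirit of the
standard implementations, and is deterministic under seed. Binary-scale
proportion mediated is `nie / (nde + nie)` and is flagged rather than
reported when the two effects disagree in sign. Significance families
for mediation are supplied by the caller (`classify_mediation()`'s
threshold) rather than hard-coded, because the appropriate family size
depends on how many mediator-outcome pairs a study actually tests. The
mediator-outcome confounding sensitivity analysis evaluates
`nie(rho) = a * (b - rho * sigma_y / sigma_m)` on a correlation grid;
exposure-mediator confounding is assumed absent because a germline score
is fixed at birth.

## Mendelian randomisation

Harmonization aligns effect alleles, negating outcome betas for swapped
labels; palindromic variants are aligned by allele frequency and dropped
when `min(eaf, 1-eaf) > 0.42` on either side (a standard ambiguity
cut-off). Instrument QC removes F < 10 and variants that are pQTLs for
five or more proteins, and skips proteins with fewer than three cis
instruments in cis-only mode. The estimators:

* **IVW** is the fixed-effect form (weighted least squares through the
  origin, weights `1/se_y²`), reducing to the Wald ratio at one
  instrument; Cochran's Q is reported for heterogeneity transparency. A
  multiplicative random-effects variant was not adopted because the
  consensus rule, not any single estimator, carries the inference.
* **Simple/weighted medians** use the interpolated cumulative-weight
  rule (`p_j = (S_j - w_j/2) / W`, linear interpolation to 0.5) with a
  parametric bootstrap SE (1000 draws, seeded).
* **MR-Egger** orients all exposure betas non-negative and fits weighted
  least squares with an intercept; the intercept t-test (df J-2) is the
  directional-pleiotropy gate at p < 0.05.

The consensus is the median of the four method p-values (the mean of the
2nd and 3rd order statistics), with BH FDR across proteins and a
Bonferroni level of `alpha / (proteins x 4)` — 4.3e-6 at the
2922-protein scale; pleiotropy-flagged proteins are excluded from the
significant set regardless of consensus p. MVMR fits both exposures
jointly by WLS without intercept; the pleiotropy Q uses J-2 df, and the
conditional F-statistic for one exposure is the weighted residual sum of
squares from regressing its betas on the other exposure's, divided by
J-1 — published df conventions differ, so this convention is validated
by its own calibration tests rather than by equality with any package.
An analysis is retained only with both conditional F > 10 and Q p >
0.05.

## Colocalization

Per-variant Wakefield log approximate Bayes factors use prior SDs of
`0.15 * sdY` for quantitative traits (sdY = 1 for standardized proteins,
assumed rather than estimated) and 0.20 for case-control log odds; the
variant-level priors are p1 = p2 = 1e-4 and p12 = 1e-5. All hypothesis
weights are accumulated in log space, with H3 computed as
`logdiff(L1 + L2, L12)` and guarded to -Inf on underflow, so extreme
Bayes factors cannot overflow. The decision rule is
`PP.H3 + PP.H4 > 0.99` and `PP.H4 / PP.H3 > 5` (infinite ratio when
PP.H3 is exactly zero). Candidate regions seed on variants with p < 1e-6
in *both* GWAS, a 250 kb half-window each side, and overlapping seeds
merged; a single causal variant per trait per region is assumed
(fine-mapped multi-signal colocalization is out of scope and stated in
output metadata).

## Trial survival analysis

Cox fits go through `survival::coxph()` with Efron ties, the field's
reference implementation, and the test suite checks the estimate against
a brute-force partial-likelihood grid search. The proportional-hazards
diagnostic is `survival::cox.zph()` on the Kaplan-Meier-transformed time
axis (identity and rank transforms available); models with global
p < 0.05 are flagged, never dropped. Endpoint scans apply Bonferroni
across proteins x endpoints in the discovery role and BH FDR restricted
to discovery hits in replication. Covariate tiers are nested (base ⊂
clinical ⊂ clinical + NT-proBNP) with endpoint-specific clinical sets.
Competing risk of death is handled by censoring. Repeat-measurement
modes fit baseline, repeat, and repeat-adjusted-for-baseline exposures
side by side; a systematically larger repeat hazard ratio is read as
cumulative exposure or reverse causation, which the generator's scenario
reproduces.

## Enrichment

Over-representation is the upper-tail hypergeometric `P[X >= k]` with
the statistical domain restricted to the assayed background (pathways
are intersected with the background before testing), and BH FDR across
pathways. BH replaces the multiple-testing adjustment built into the
usual web tool because that algorithm is not publishable or testable;
the substitution is declared, not inferred. Depletion is out of scope.

# Problem sizes and determinism

The default configuration runs the full pipeline in roughly two minutes
on one core: 4000/2000 cohort strata, 4000-sample pQTL GWAS,
10,000-sample outcome GWAS, 50 proteins x 20-variant cis regions, 50
score variants. Calibration analyses use summary-level simulation (600
replicates for IVW and Egger, 500 for the MVMR Q and the PH test), and
discrimination analyses use reduced single-protein cohorts so that a
hundred replicates stay cheap. Every stage derives its seed from the
configuration seed, so identical configurations give byte-identical
outputs, including all written TSVs (the recorded manifest omits
wall-times for this reason).

# What passing tests do and do not show

The generator emulates the *statistical structure* the methods assume:
AR(1) LD, Gaussian standardized proteins, logistic liability disease,
exponential trial hazards, non-overlapping GWAS samples. It does not
emulate real human LD panels, relatedness, ancestry admixture (strata
are labels), assay batch effects, non-Gaussian protein distributions, or
phenotype misclassification. Calibration and recovery on these synthetic
cohorts therefore demonstrate that the estimators and decision rules are
implemented correctly and behave as designed under their own
assumptions — not that those assumptions hold in any particular real
cohort. Known limitations carried over from the analytical design
itself: fixed-effect IVW understates uncertainty under heterogeneity
(Cochran's Q is reported so users can see it), the single-causal-variant
coloc assumption fails in multi-signal regions, and binary-outcome
natural effects are interpreted on the log-odds scale, which is
non-collapsible across covariate sets.
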