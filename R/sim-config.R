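#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles every knob of the data-generating model into a validated list.
#' The defaults define desk-scale study conditions: a discovery/replication
#' biobank split (4000/2000), a non-overlapping pQTL-exposure sample and a
#' larger binary-trait outcome GWAS sample for two-sample MR, 50 proteins
#' each with a 20-variant cis region, and a PGS -> BMI -> protein ->
#' incident-disease mediation chain with a tunable mediated fraction.
#'
#' @param n_discovery,n_replication sample sizes of the discovery and
#'   replication strata of the biobank-style cohort.
#' @param n_gwas_exposure sample size of the stratum used for protein
#'   (pQTL) GWAS, non-overlapping with the outcome GWAS.
#' @param n_gwas_outcome sample size of the stratum used for the binary
#'   disease GWAS (the MR outcome side).
#' @param n_proteins number of circulating proteins.
#' @param n_variants_per_cis_region variants per protein cis region.
#' @param ld_rho first-order autoregressive haplotype correlation between
#'   adjacent variants within a region, in `[0, 1)`.
#' @param maf_range length-2 ordered vector of minor-allele frequencies in
#'   `(0, 0.5]`; each region draws its MAF uniformly from this range.
#' @param pgs_n_variants number of (mutually independent) variants carrying
#'   the polygenic-score architecture of the index disease.
#' @param mediated_fraction fraction of the total PGS effect on a target
#'   protein that flows through BMI, in `[0, 1]`.
#' @param protein_h2_cis proportion of protein variance explained by its
#'   cis region.
#' @param disease_prevalence target incident-disease fraction; the liability
#'   intercept is calibrated to it by root finding.
#' @param trial_log_hr per-SD log hazard ratio of each trial-causal protein.
#' @param censor_rate exponential censoring rate (events per year) in the
#'   simulated trial; must be > 0.
#' @param seed integer seed; identical configuration and seed give
#'   bit-identical outputs everywhere downstream.
#' @param n_pgs_targets number of proteins with a nonzero total PGS effect.
#' @param n_causal_proteins number of proteins with a true causal effect on
#'   disease liability (the MR-positive set).
#' @param n_reverse_proteins number of proteins whose levels respond to the
#'   disease genetic liability (reverse-causation scenario; default 0).
#' @param n_coloc_distinct number of non-causal proteins whose cis region
#'   contains a distinct disease-causal variant (coloc H3 scenario).
#' @param pgs_bmi_effect per-SD effect of the true PGS on BMI.
#' @param pgs_protein_total total per-SD PGS effect on each target protein.
#' @param protein_disease_logodds liability log-odds per SD of each causal
#'   protein.
#' @param disease_pgs_logodds direct liability log-odds per SD of the true
#'   PGS (the trait's own polygenic architecture).
#' @param distinct_variant_logodds per-allele liability log-odds of each
#'   planted distinct coloc variant.
#' @param reverse_protein_effect per-SD effect of the disease genetic
#'   liability on each reverse-scenario protein.
#' @param prevalent_rate marginal probability of prevalent (baseline)
#'   disease, drawn independently of the incident liability.
#' @param n_causal_cis causal variants per cis region (spread across the
#'   region so they survive LD clumping).
#' @param test_retest_r correlation between the two trial protein
#'   timepoints.
#' @param trial_followup administrative end of trial follow-up (years).
#' @param n_trial_causal number of proteins with a nonzero trial log-HR.
#'
#' @return a list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_proteins = 4, seed = 7)
#' cfg$n_discovery
sim_config <- function(n_discovery = 4000,
                       n_replication = 2000,
                       n_gwas_exposure = 4000,
                       n_gwas_outcome = 10000,
                       n_proteins = 50,
                       n_variants_per_cis_region = 20,
                       ld_rho = 0.5,
                       maf_range = c(0.05, 0.5),
                       pgs_n_variants = 50,
                       mediated_fraction = 0.25,
                       protein_h2_cis = 0.2,
                       disease_prevalence = 0.1,
                       trial_log_hr = 0.3,
                       censor_rate = 0.1,
                       seed = 1L,
                       n_pgs_targets = 10,
                       n_causal_proteins = 10,
                       n_reverse_proteins = 0,
                       n_coloc_distinct = 3,
                       pgs_bmi_effect = 0.3,
                       pgs_protein_total = 0.15,
                       protein_disease_logodds = 0.8,
                       disease_pgs_logodds = 0.5,
                       distinct_variant_logodds = 0.4,
                       reverse_protein_effect = 0.5,
                       prevalent_rate = 0.05,
                       n_causal_cis = 5,
                       test_retest_r = 0.7,
                       trial_followup = 5,
                       n_trial_causal = 5) {
  cfg <- as.list(environment())

  for (nm in c("n_discovery", "n_replication", "n_gwas_exposure",
               "n_gwas_outcome", "n_proteins", "n_variants_per_cis_region",
               "pgs_n_variants")) {
    check_number(cfg[[nm]], nm, lower = 1, integer = TRUE)
  }
  for (nm in c("n_pgs_targets", "n_causal_proteins", "n_reverse_proteins",
               "n_coloc_distinct", "n_causal_cis", "n_trial_causal")) {
    check_number(cfg[[nm]], nm, lower = 0, integer = TRUE)
  }
  check_number(ld_rho, "ld_rho", lower = 0, upper = 1, open_upper = TRUE)
  check_that(is.numeric(maf_range) && length(maf_range) == 2 &&
               all(is.finite(maf_range)) && maf_range[1] <= maf_range[2] &&
               maf_range[1] > 0 && maf_range[2] <= 0.5,
             "`maf_range` must be an ordered pair in (0, 0.5]")
  for (nm in c("mediated_fraction", "protein_h2_cis", "disease_prevalence",
               "prevalent_rate")) {
    check_number(cfg[[nm]], nm, lower = 0, upper = 1)
  }
  check_number(disease_prevalence, "disease_prevalence",
               lower = 0, upper = 1, open_lower = TRUE, open_upper = TRUE)
  check_number(censor_rate, "censor_rate", lower = 0, open_lower = TRUE)
  check_number(trial_log_hr, "trial_log_hr")
  check_number(test_retest_r, "test_retest_r", lower = -1, upper = 1)
  check_number(trial_followup, "trial_followup", lower = 0, open_lower = TRUE)
  check_number(seed, "seed", integer = TRUE)
  check_that(n_causal_cis <= n_variants_per_cis_region,
             "n_causal_cis exceeds the cis region size")
  check_that(n_pgs_targets + n_causal_proteins + n_reverse_proteins +
               n_coloc_distinct <= n_proteins,
             "protein scenario counts exceed n_proteins")

  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cohort: %d discovery + %d replication; GWAS: %d exposure / %d outcome\n",
              x$n_discovery, x$n_replication, x$n_gwas_exposure, x$n_gwas_outcome))
  cat(sprintf("  proteins: %d (%d PGS targets, %d disease-causal, %d reverse)\n",
              x$n_proteins, x$n_pgs_targets, x$n_causal_proteins, x$n_reverse_proteins))
  cat(sprintf("  cis regions: %d variants, LD rho %.2f, h2_cis %.2f; PGS variants: %d\n",
              x$n_variants_per_cis_region, x$ld_rho, x$protein_h2_cis, x$pgs_n_variants))
  cat(sprintf("  mediated fraction %.2f; prevalence %.2f; trial log-HR %.2f; seed %d\n",
              x$mediated_fraction, x$disease_prevalence, x$trial_log_hr, x$seed))
  invisible(x)
}

# Total samples across the four strata.
total_samples <- function(config) {
  config$n_discovery + config$n_replication +
    config$n_gwas_exposure + config$n_gwas_outcome
}

# Stratum labels in generation order.
stratum_labels <- function(config) {
  rep(c("discovery", "replication", "gwas_exposure", "gwas_outcome"),
      times = c(config$n_discovery, config$n_replication,
                config$n_gwas_exposure, config$n_gwas_outcome))
}
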