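#' Simulate the biobank-style cohort and its ground-truth ledger
#'
#' Builds phenotypes on top of a simulated genotype matrix following the
#' causal structure the downstream analyses assume:
#'
#' * a true polygenic score `PGS = sum w_j dosage_j` over the PGS variants,
#'   standardized in-sample;
#' * `BMI = gamma * PGS + covariate terms + noise`;
#' * each protein is the sum of its cis-region effects (variance share
#'   `protein_h2_cis`), a direct PGS effect `delta`, a BMI effect `b`
#'   scaled so that `gamma * b / (gamma * b + delta)` equals
#'   `mediated_fraction` for PGS-target proteins, an optional
#'   reverse-causation term, and Gaussian noise topping variance up to 1;
#' * incident disease is a logistic liability in the causal proteins, BMI,
#'   the direct polygenic term, planted distinct-locus variants, and
#'   covariates, with the intercept calibrated by root finding so the
#'   incident fraction matches `disease_prevalence`; prevalent disease is
#'   an independent baseline flag and forces `incident = 0`.
#'
#' Every nonzero coefficient is recorded once in the returned truth ledger,
#' which suffices to compute the expected result of every downstream
#' recovery analysis.
#'
#' @param config a [sim_config()].
#' @param genotypes the matching [simulate_genotypes()] output.
#' @return a list with `cohort` (tibble, one row per sample across all four
#'   strata) and `truth` (a `truth_ledger`: `$proteins`, `$variants`,
#'   `$globals`).
#' @export
simulate_cohort <- function(config, genotypes) {
  check_that(inherits(config, "sim_config"), "`config` must be a sim_config")
  check_that(inherits(genotypes, "genotype_matrix"),
             "`genotypes` must come from simulate_genotypes()")
  n <- length(genotypes$sample_ids)
  check_that(n == total_samples(config),
             "genotype matrix size does not match the configuration")
  set.seed(derive_seed(config$seed, "cohort"))

  v <- genotypes$variants
  scen <- protein_scenarios(config)

  # --- covariates -----------------------------------------------------------
  age <- rnorm(n, 58, 8)
  sex <- rbinom(n, 1L, 0.5)
  pcs <- matrix(rnorm(n * 10L), nrow = n,
                dimnames = list(NULL, paste0("pc", 1:10)))
  age_std <- (age - 58) / 8

  # --- true polygenic score -------------------------------------------------
  pgs_ids <- v$variant_id[v$chrom == config$n_proteins + 1L]
  hub_id <- trans_hub_id(config)
  w <- rnorm(length(pgs_ids))
  names(w) <- pgs_ids
  if (!is.null(hub_id)) w[hub_id] <- 0
  G_pgs <- dosage_cols(genotypes, pgs_ids)
  pgs_raw <- drop(G_pgs %*% w)
  pgs_true <- standardize(pgs_raw, "pgs_true")
  # per-allele weights on the standardized scale
  w_std <- w / sd(pgs_raw)

  # --- BMI ------------------------------------------------------------------
  gamma <- config$pgs_bmi_effect
  bmi_age <- 0.05; bmi_sex <- 0.1
  var_bmi_resid <- 1 - gamma^2 - bmi_age^2 - bmi_sex^2 * 0.25
  check_that(var_bmi_resid > 0, "BMI variance components exceed 1")
  bmi <- gamma * pgs_true + bmi_age * age_std + bmi_sex * (sex - 0.5) +
    rnorm(n, 0, sqrt(var_bmi_resid))
  wc <- 0.8 * bmi + sqrt(1 - 0.8^2) * rnorm(n)
  whr <- 0.6 * bmi + sqrt(1 - 0.6^2) * rnorm(n)

  # --- proteins -------------------------------------------------------------
  mf <- config$mediated_fraction
  tau <- config$pgs_protein_total
  delta_target <- (1 - mf) * tau
  b_target <- if (gamma > 0) mf * tau / gamma else 0

  m_cis <- config$n_variants_per_cis_region
  causal_idx <- unique(round(seq(1, m_cis, length.out = config$n_causal_cis)))
  proteins <- matrix(0, nrow = n, ncol = config$n_proteins,
                     dimnames = list(NULL, scen$protein_id))
  variant_truth <- list()
  hub_targets <- trans_hub_targets(config)
  if (!is.null(hub_id)) hub_dos <- dosage_cols(genotypes, hub_id)[, 1]

  for (p in seq_len(config$n_proteins)) {
    pid <- scen$protein_id[p]
    cis_ids <- v$variant_id[v$protein_id %in% pid]
    f <- v$maf[match(cis_ids[1], v$variant_id)]
    var_dos <- 2 * f * (1 - f)
    beta_cis <- rep(0, length(cis_ids))
    # geometrically decaying variance shares: equal shares would give every
    # instrument the same |beta| and leave Egger regression unidentified
    share <- 0.6^(seq_along(causal_idx) - 1)
    share <- config$protein_h2_cis * share / sum(share)
    beta_cis[causal_idx] <- sqrt(share / var_dos) *
      rep_len(c(1, -1), length(causal_idx))
    G_cis <- dosage_cols(genotypes, cis_ids)
    cis_part <- drop(G_cis %*% beta_cis)

    delta <- if (scen$scenario[p] == "target") delta_target else 0
    b_p <- if (scen$scenario[p] == "target") b_target else 0
    kappa <- if (scen$scenario[p] == "reverse") config$reverse_protein_effect else 0
    beta_hub <- 0
    if (!is.null(hub_id) && p %in% hub_targets) {
      beta_hub <- sqrt(0.02 / (2 * v$maf[match(hub_id, v$variant_id)] *
                                 (1 - v$maf[match(hub_id, v$variant_id)])))
    }

    # genetic path through the PGS: delta (direct) + b (via BMI) + kappa
    # (reverse); with BMI = gamma*PGS + e its variance is
    # (delta + kappa + b*gamma)^2 + b^2 * (1 - gamma^2)
    path_coef <- delta + kappa
    var_path <- (path_coef + b_p * gamma)^2 + b_p^2 * (1 - gamma^2)
    var_resid <- 1 - config$protein_h2_cis - var_path - beta_hub^2 * 0.42
    check_that(var_resid > 0,
               "protein_h2_cis plus the other variance components exceed 1 for %s", pid)

    proteins[, p] <- cis_part + path_coef * pgs_true + b_p * bmi +
      (if (beta_hub != 0) beta_hub * hub_dos else 0) +
      rnorm(n, 0, sqrt(var_resid))

    variant_truth[[p]] <- tibble(
      variant_id = cis_ids[causal_idx],
      protein_id = pid,
      beta_protein = beta_cis[causal_idx],
      disease_logodds = 0
    )
    if (beta_hub != 0) {
      variant_truth[[p]] <- bind_rows(
        variant_truth[[p]],
        tibble(variant_id = hub_id, protein_id = pid,
               beta_protein = beta_hub, disease_logodds = 0)
      )
    }
  }

  # --- disease liability ----------------------------------------------------
  causal_p <- which(scen$scenario == "causal")
  theta <- rep(0, config$n_proteins)
  theta[causal_p] <- config$protein_disease_logodds
  bmi_logodds <- 0.2

  distinct_p <- which(scen$scenario == "distinct")
  distinct_truth <- list()
  distinct_part <- 0
  if (length(distinct_p) > 0) {
    gap_idx <- pick_distinct_index(m_cis, causal_idx)
    for (p in distinct_p) {
      pid <- scen$protein_id[p]
      did <- v$variant_id[v$protein_id %in% pid][gap_idx]
      distinct_part <- distinct_part +
        config$distinct_variant_logodds * dosage_cols(genotypes, did)[, 1]
      distinct_truth[[length(distinct_truth) + 1L]] <- tibble(
        variant_id = did, protein_id = pid,
        beta_protein = 0, disease_logodds = config$distinct_variant_logodds
      )
    }
  }

  eta <- config$disease_pgs_logodds * pgs_true +
    drop(proteins %*% theta) + bmi_logodds * bmi + distinct_part +
    0.2 * age_std + 0.1 * (sex - 0.5)
  alpha0 <- uniroot(function(a) mean(plogis(a + eta)) - config$disease_prevalence,
                    interval = c(-30, 30), tol = 1e-10)$root
  incident <- rbinom(n, 1L, plogis(alpha0 + eta))
  prevalent <- rbinom(n, 1L, config$prevalent_rate)
  incident[prevalent == 1L] <- 0L

  cohort <- tibble(
    sample_id = genotypes$sample_ids,
    stratum = stratum_labels(config),
    age = age, sex = sex
  ) %>%
    bind_cols(as_tibble(pcs)) %>%
    mutate(bmi = bmi, wc = wc, whr = whr, pgs_true = pgs_true) %>%
    bind_cols(as_tibble(proteins)) %>%
    mutate(prevalent_disease = prevalent,
           incident_disease = incident,
           followup_time = runif(n, 5, 14))

  # trial-causal proteins: lead with PGS targets (so the PGS -> protein ->
  # trial-event mediation chain exists), fill with disease-causal proteins
  target_p <- which(scen$scenario == "target")
  trial_idx <- head(c(head(target_p, 2), causal_p),
                    config$n_trial_causal)
  truth <- structure(list(
    proteins = scen %>%
      mutate(
        pgs_total = ifelse(scenario == "target", tau,
                    ifelse(scenario == "reverse",
                           config$reverse_protein_effect, 0)),
        pgs_direct = ifelse(scenario == "target", delta_target, 0),
        bmi_effect = ifelse(scenario == "target", b_target, 0),
        mediated_fraction = ifelse(scenario == "target", mf, NA_real_),
        disease_logodds = theta,
        reverse_effect = ifelse(scenario == "reverse",
                                config$reverse_protein_effect, 0),
        trial_log_hr = ifelse(row_number() %in% trial_idx,
                              config$trial_log_hr, 0),
        coloc_scenario = ifelse(scenario == "causal", "shared",
                         ifelse(scenario == "distinct", "distinct", "null"))
      ),
    variants = bind_rows(
      bind_rows(variant_truth),
      bind_rows(distinct_truth),
      tibble(variant_id = pgs_ids, protein_id = NA_character_,
             beta_protein = 0, disease_logodds = 0)
    ) %>%
      mutate(pgs_weight = unname(w_std[variant_id])) %>%
      mutate(pgs_weight = ifelse(is.na(pgs_weight), 0, pgs_weight)),
    globals = list(
      gamma = gamma, tau = tau, mediated_fraction = mf,
      disease_pgs_logodds = config$disease_pgs_logodds,
      bmi_disease_logodds = bmi_logodds, alpha0 = alpha0,
      trans_hub = hub_id, trans_hub_targets = hub_targets,
      causal_cis_index = causal_idx
    )
  ), class = "truth_ledger")

  list(cohort = cohort, truth = truth)
}

# Deterministic scenario assignment: targets first, then disease-causal,
# reverse-causation, distinct-coloc, and null proteins.
protein_scenarios <- function(config) {
  scenario <- rep("null", config$n_proteins)
  i <- 1L
  take <- function(k) {
    idx <- seq.int(i, length.out = k)
    i <<- i + k
    idx
  }
  if (config$n_pgs_targets > 0) scenario[take(config$n_pgs_targets)] <- "target"
  if (config$n_causal_proteins > 0) scenario[take(config$n_causal_proteins)] <- "causal"
  if (config$n_reverse_proteins > 0) scenario[take(config$n_reverse_proteins)] <- "reverse"
  if (config$n_coloc_distinct > 0) scenario[take(config$n_coloc_distinct)] <- "distinct"
  tibble(protein_id = sprintf("protein_%02d", seq_len(config$n_proteins)),
         scenario = scenario)
}

# The last PGS-chromosome variant doubles as a trans-pQTL hub (weight 0 in
# the polygenic score) hitting 6 proteins, to exercise the >= 5-protein
# pleiotropy filter. Only created when the simulation is large enough.
trans_hub_id <- function(config) {
  if (config$pgs_n_variants >= 5 && config$n_proteins >= 6)
    sprintf("pgs_v%03d", config$pgs_n_variants)
  else NULL
}

trans_hub_targets <- function(config) {
  if (is.null(trans_hub_id(config))) return(integer(0))
  seq.int(config$n_proteins - 5L, config$n_proteins)
}

# Cis index maximally separated from the causal set (distinct-coloc locus).
pick_distinct_index <- function(m, causal_idx) {
  cand <- setdiff(seq_len(m), causal_idx)
  cand[which.max(vapply(cand, function(j) min(abs(j - causal_idx)), numeric(1)))]
}

#' @export
print.truth_ledger <- function(x, ...) {
  cat(sprintf("<truth_ledger> %d proteins (%s)\n", nrow(x$proteins),
              paste(sprintf("%s: %d", names(table(x$proteins$scenario)),
                            table(x$proteins$scenario)), collapse = ", ")))
  invisible(x)
}

#' True polygenic-score weights as a weight set
#'
#' Extracts the generator's per-allele standardized-score weights from a
#' truth ledger in the weight-file layout accepted by [compute_pgs()].
#'
#' @param truth a `truth_ledger` from [simulate_cohort()].
#' @param score_id label for the resulting score.
#' @return a weight-set tibble (`variant_id`, `effect_allele`,
#'   `other_allele`, `weight`, `score_id`).
#' @export
truth_weightset <- function(truth, score_id = "pgs_true") {
  check_that(inherits(truth, "truth_ledger"), "`truth` must be a truth_ledger")
  truth$variants %>%
    filter(.data$pgs_weight != 0) %>%
    distinct(.data$variant_id, .keep_all = TRUE) %>%
    mutate(effect_allele = "A", other_allele = "G",
           weight = .data$pgs_weight, score_id = score_id) %>%
    select("variant_id", "effect_allele", "other_allele", "weight", "score_id")
}
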