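#' Simulate trial-like censored survival data with two protein timepoints
#'
#' Builds a randomized-trial table from a (subset of a) simulated cohort:
#' exponential event times for three endpoints (`mace`, `hhf`, `renal`)
#' with log-hazard `trial_log_hr * protein` summed over the trial-causal
#' proteins plus age/sex and clinical risk-factor terms, independent
#' exponential censoring at `censor_rate` and an administrative end at
#' `trial_followup` years, a 1:1 treatment-arm flag (the analyses restrict
#' to the placebo arm; the arm itself carries no effect), and baseline plus
#' repeat protein measurements with test-retest correlation
#' `test_retest_r`.
#'
#' Two optional scenario switches exist so the diagnostic analyses have
#' something to find: `reverse_causation` adds a latent-risk term to the
#' repeat (t1) measurement of the causal proteins only, so repeat-based
#' hazard ratios inflate relative to baseline; `confounded_protein`
#' redefines the last protein as a proxy of baseline eGFR (which itself
#' drives the hazard), so its association vanishes once the clinical tier
#' adjusts for eGFR.
#'
#' @param config a [sim_config()].
#' @param cohort cohort rows to enrol (typically one stratum).
#' @param truth the matching truth ledger (identifies causal proteins).
#' @param reverse_causation logical scenario switch (default `FALSE`).
#' @param confounded_protein logical scenario switch (default `TRUE`).
#' @return a tibble with `sample_id`, `arm`, covariates, clinical risk
#'   factors, `ntprobnp`, per-endpoint `time_*`/`event_*`, and
#'   `<protein>_t0` / `<protein>_t1` columns. Attribute
#'   `confounded_protein` names the eGFR-proxy protein (or `NA`).
#' @export
simulate_trial <- function(config, cohort, truth,
                           reverse_causation = FALSE,
                           confounded_protein = TRUE) {
  check_that(inherits(config, "sim_config"), "`config` must be a sim_config")
  check_number(config$censor_rate, "censor_rate", lower = 0, open_lower = TRUE)
  n <- nrow(cohort)
  check_that(n > 0, "empty cohort")
  set.seed(derive_seed(config$seed, "trial"))

  prot_ids <- truth$proteins$protein_id
  P0 <- as.matrix(cohort[, prot_ids])
  age_std <- (cohort$age - 58) / 8
  sex <- cohort$sex

  # clinical risk factors (standardized scales / binary flags)
  egfr <- rnorm(n)
  sbp <- rnorm(n)
  hba1c <- rnorm(n)
  uacr <- rnorm(n)
  prior_hf <- rbinom(n, 1L, 0.15)
  afib <- rbinom(n, 1L, 0.10)
  cad <- rbinom(n, 1L, 0.30)
  hypertension <- rbinom(n, 1L, 0.50)
  smoking <- rbinom(n, 1L, 0.12)

  conf_id <- NA_character_
  if (isTRUE(confounded_protein)) {
    # last protein becomes an eGFR proxy with no hazard of its own
    conf_id <- tail(prot_ids, 1)
    P0[, conf_id] <- 0.8 * egfr + 0.6 * rnorm(n)
  }

  loghr <- truth$proteins$trial_log_hr
  names(loghr) <- prot_ids
  if (!is.na(conf_id)) loghr[conf_id] <- 0
  prot_term <- drop(P0 %*% loghr)

  lp <- list(
    mace  = prot_term + 0.3 * age_std + 0.2 * sex + 0.2 * cad + 0.15 * smoking,
    hhf   = prot_term + 0.3 * age_std + 0.2 * sex + 0.4 * prior_hf - 0.3 * egfr,
    renal = prot_term + 0.3 * age_std + 0.2 * sex - 0.4 * egfr + 0.25 * uacr
  )
  base_rate <- c(mace = 0.04, hhf = 0.025, renal = 0.025)
  ntprobnp <- 0.5 * standardize(lp$hhf) + sqrt(1 - 0.25) * rnorm(n)

  out <- tibble(
    sample_id = cohort$sample_id,
    arm = rbinom(n, 1L, 0.5),
    age = cohort$age, sex = sex
  ) %>%
    bind_cols(cohort[, paste0("pc", 1:10)]) %>%
    mutate(egfr = egfr, sbp = sbp, hba1c = hba1c, uacr = uacr,
           prior_hf = prior_hf, afib = afib, cad = cad,
           hypertension = hypertension, smoking = smoking,
           ntprobnp = ntprobnp)

  for (e in names(lp)) {
    t_event <- rexp(n, rate = base_rate[[e]] * exp(lp[[e]]))
    t_cens <- pmin(rexp(n, rate = config$censor_rate), config$trial_followup)
    out[[paste0("time_", e)]] <- pmin(t_event, t_cens)
    out[[paste0("event_", e)]] <- as.integer(t_event <= t_cens)
  }

  r <- config$test_retest_r
  # reverse causation: the developing disease state raises the repeat
  # measurement, most strongly in subjects whose renal event came early
  early_disease <- out$event_renal *
    exp(-out$time_renal / config$trial_followup)
  causal_ids <- prot_ids[loghr != 0]
  lam <- sqrt(max(0, r))
  for (pid in prot_ids) {
    if (isTRUE(reverse_causation) && pid %in% causal_ids) {
      # both timepoints are noisy measurements of the hazard-driving level
      # (test-retest correlation r); the repeat additionally reflects early
      # disease, so repeat-based hazard ratios inflate and adjusting for
      # baseline ameliorates part of the inflation
      t0 <- lam * P0[, pid] + sqrt(max(0, 1 - r)) * rnorm(n)
      t1 <- lam * P0[, pid] + sqrt(max(0, 1 - r)) * rnorm(n) +
        0.35 * early_disease
    } else {
      t0 <- P0[, pid]
      t1 <- r * t0 + sqrt(max(0, 1 - r^2)) * rnorm(n)
    }
    out[[paste0(pid, "_t0")]] <- t0
    out[[paste0(pid, "_t1")]] <- t1
  }

  attr(out, "confounded_protein") <- conf_id
  attr(out, "protein_ids") <- prot_ids
  out
}
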