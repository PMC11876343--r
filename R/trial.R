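#' Tier covariate sets for the trial endpoint models
#'
#' `base`: age, sex, age x sex, genetic PCs 1-10. `clinical` adds
#' endpoint-specific risk factors (heart-failure endpoints: coronary
#' artery disease, atrial fibrillation, baseline eGFR, albuminuria/UACR,
#' prior heart failure; MACE: hypertension, smoking, prior
#' atherosclerotic disease; renal: baseline eGFR, UACR, systolic blood
#' pressure, HbA1c). `clinical_plus_ntprobnp` further adds NT-proBNP.
#' The sets are nested: base is contained in clinical, which is contained
#' in clinical_plus_ntprobnp.
#'
#' @param endpoint `"mace"`, `"hhf"`, or `"renal"`.
#' @param tier `"base"`, `"clinical"`, or `"clinical_plus_ntprobnp"`.
#' @return character vector of covariate column names.
#' @export
tier_covariates <- function(endpoint = c("mace", "hhf", "renal"),
                            tier = c("base", "clinical",
                                     "clinical_plus_ntprobnp")) {
  endpoint <- match.arg(endpoint)
  tier <- match.arg(tier)
  base <- c("age", "sex", "age_sex", paste0("pc", 1:10))
  clinical <- switch(endpoint,
    mace = c("hypertension", "smoking", "cad"),
    hhf = c("cad", "afib", "egfr", "uacr", "prior_hf"),
    renal = c("egfr", "uacr", "sbp", "hba1c", "cad", "prior_hf")
  )
  out <- switch(tier,
    base = base,
    clinical = c(base, clinical),
    clinical_plus_ntprobnp = c(base, clinical, "ntprobnp")
  )
  out
}

#' Cox proportional-hazards fit for one protein term
#'
#' Efron-tie partial-likelihood fit of
#' `Surv(time, event) ~ protein + covariates` via [survival::coxph()],
#' reporting the protein term with Wald inference, the hazard ratio with
#' its 95% CI `exp(estimate -/+ 1.96 se)`, and the global
#' proportional-hazards test p-value from scaled Schoenfeld residuals on
#' the Kaplan-Meier-transformed time axis.
#'
#' @param records data frame with `time`, `event`, the protein column,
#'   and covariates.
#' @param protein_term protein column name.
#' @param covariates character vector of covariate columns.
#' @param tie_method `"efron"` (default) or `"breslow"`.
#' @param ph_transform time transform for the PH test (`"km"`,
#'   `"identity"`, or `"rank"`).
#' @return a one-row `cox_fit` tibble: `term`, `estimate` (log-HR per
#'   unit), `se`, `hazard_ratio`, `ci_low`, `ci_high`, `wald_p`, `n`,
#'   `n_events`, `ph_global_p`, `converged`. The underlying `coxph`
#'   object is kept in attribute `fit`.
#' @export
cox_fit <- function(records, protein_term, covariates = character(0),
                    tie_method = c("efron", "breslow"),
                    ph_transform = "km") {
  tie_method <- match.arg(tie_method)
  cols <- c("time", "event", protein_term, covariates)
  check_that(all(cols %in% names(records)),
             "missing column(s): %s",
             paste(setdiff(cols, names(records)), collapse = ", "))
  d <- records[complete.cases(records[, cols]), cols, drop = FALSE]
  check_that(all(d$time > 0), "non-positive survival times")
  n_events <- sum(d$event)
  check_that(n_events >= 1, "no events in the data")
  const <- vapply(c(protein_term, covariates),
                  function(cn) var(d[[cn]]) < 1e-12, logical(1))
  if (any(const)) {
    stop("degenerate design; constant column(s): ",
         paste(names(const)[const], collapse = ", "), call. = FALSE)
  }

  rhs <- paste(c(sprintf("`%s`", protein_term),
                 sprintf("`%s`", covariates)), collapse = " + ")
  form <- as.formula(paste("survival::Surv(time, event) ~", rhs))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(form, data = d, ties = tie_method,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be", conditionMessage(w))) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    }
  )
  co <- summary(fit)$coefficients
  est <- co[1, "coef"]
  se <- co[1, "se(coef)"]

  ph_p <- tryCatch({
    if (n_events >= 3) {
      zp <- survival::cox.zph(fit, transform = ph_transform, global = TRUE)
      zp$table["GLOBAL", "p"]
    } else NA_real_
  }, error = function(e) NA_real_)

  out <- tibble(
    term = protein_term,
    estimate = est, se = se,
    hazard_ratio = exp(est),
    ci_low = exp(est - qnorm(0.975) * se),
    ci_high = exp(est + qnorm(0.975) * se),
    wald_p = co[1, "Pr(>|z|)"],
    n = nrow(d), n_events = n_events,
    ph_global_p = ph_p,
    converged = converged
  ) %>% structure(class = c("cox_fit", class(tibble())))
  attr(out, "fit") <- fit
  out
}

#' Proportional-hazards diagnostic for a fitted Cox model
#'
#' Scaled Schoenfeld residuals regressed on the transformed event times
#' ([survival::cox.zph()]); per-term score tests and the global
#' chi-square. Models with global p < `flag_alpha` are flagged, not
#' dropped.
#'
#' @param fit a `cox_fit` (or `coxph` object).
#' @param transform `"km"` (default), `"identity"`, or `"rank"`.
#' @param flag_alpha flag level for the global test.
#' @return list with `table` (per-term + GLOBAL rows as a tibble),
#'   `global_p`, `flagged`, and `skip_reason` (`NA` normally; set with
#'   `table = NULL` when fewer than 3 events).
#' @export
ph_test <- function(fit, transform = "km", flag_alpha = 0.05) {
  cx <- if (inherits(fit, "cox_fit")) attr(fit, "fit") else fit
  check_that(inherits(cx, "coxph"), "`fit` must be a cox_fit or coxph object")
  n_events <- cx$nevent
  if (is.null(n_events)) n_events <- sum(cx$y[, ncol(cx$y)])
  if (n_events < 3) {
    return(list(table = NULL, global_p = NA_real_, flagged = NA,
                skip_reason = "fewer than 3 events"))
  }
  zp <- survival::cox.zph(cx, transform = transform, global = TRUE)
  tab <- as_tibble(zp$table, rownames = "term")
  gp <- zp$table["GLOBAL", "p"]
  list(table = tab, global_p = gp, flagged = gp < flag_alpha,
       skip_reason = NA_character_)
}

#' Protein-by-endpoint Cox scan with trial multiplicity rules
#'
#' One Cox fit per protein x endpoint at the requested covariate tier,
#' restricted to the placebo arm when an `arm` column is present.
#' Discovery applies a Bonferroni threshold across proteins x endpoints;
#' replication restricts to the supplied discovery hits and applies BH
#' FDR.
#'
#' @param trial a [simulate_trial()] table (or same layout).
#' @param protein_ids protein base names (without the `_t0` suffix);
#'   defaults to the generator's.
#' @param endpoints subset of `c("mace", "hhf", "renal")`.
#' @param tier covariate tier, see [tier_covariates()].
#' @param role `"discovery"` (Bonferroni) or `"replication"` (FDR over
#'   `discovery_hits`).
#' @param discovery_hits tibble with `protein_id`, `endpoint` (required
#'   for the replication role).
#' @param timepoint `"t0"` or `"t1"` protein measurement.
#' @param alpha significance level.
#' @param placebo_only restrict to `arm == 0`.
#' @return tibble of fits with `protein_id`, `endpoint`, `tier`, the
#'   `cox_fit` columns, and `significant` (plus `qval` for replication).
#' @export
endpoint_scan <- function(trial, protein_ids = NULL,
                          endpoints = c("mace", "hhf", "renal"),
                          tier = "base", role = c("discovery", "replication"),
                          discovery_hits = NULL, timepoint = "t0",
                          alpha = 0.05, placebo_only = TRUE) {
  role <- match.arg(role)
  protein_ids <- protein_ids %||% attr(trial, "protein_ids") %||%
    unique(sub("_t[01]$", "", grep("_t0$", names(trial), value = TRUE)))
  endpoints <- match.arg(endpoints, several.ok = TRUE)
  d <- trial
  if (placebo_only && "arm" %in% names(d)) d <- d %>% filter(.data$arm == 0)
  d$age_sex <- d$age * d$sex

  pairs <- tidyr::expand_grid(protein_id = protein_ids, endpoint = endpoints)
  if (role == "replication") {
    check_that(!is.null(discovery_hits), "replication needs discovery_hits")
    pairs <- pairs %>%
      inner_join(discovery_hits %>% select("protein_id", "endpoint"),
                 by = c("protein_id", "endpoint"))
  }
  if (nrow(pairs) == 0) {
    return(tibble(protein_id = character(), endpoint = character()))
  }

  fits <- purrr::pmap_dfr(pairs, function(protein_id, endpoint) {
    covs <- tier_covariates(endpoint, tier)
    rec <- d
    rec$time <- d[[paste0("time_", endpoint)]]
    rec$event <- d[[paste0("event_", endpoint)]]
    pcol <- paste0(protein_id, "_", timepoint)
    fit <- tryCatch(cox_fit(rec, pcol, covs),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    fit %>% mutate(protein_id = protein_id, endpoint = endpoint,
                   tier = tier, .before = 1)
  })
  if (nrow(fits) == 0) return(fits)

  if (role == "discovery") {
    thr <- alpha / nrow(pairs)
    fits %>% mutate(significant = .data$wald_p < thr)
  } else {
    fits %>% mutate(qval = bh_fdr(.data$wald_p),
                    significant = .data$qval < alpha)
  }
}

#' Baseline / repeat / repeat-adjusted protein hazard comparison
#'
#' Fits each protein against one endpoint three ways: using the baseline
#' measurement, the repeat measurement, and the repeat measurement with
#' baseline added as a covariate, and reports the hazard ratios side by
#' side. A repeat-mode hazard ratio exceeding the baseline one is the
#' signature of cumulative exposure or reverse causation.
#'
#' @param trial a trial table with `_t0` and `_t1` protein columns.
#' @param protein_ids protein base names.
#' @param endpoint one endpoint.
#' @param tier covariate tier.
#' @param placebo_only restrict to the placebo arm.
#' @return tibble with one row per protein x mode (`baseline`, `repeat`,
#'   `repeat_adjusted`) and the `cox_fit` columns.
#' @export
repeat_measurement_scan <- function(trial, protein_ids = NULL,
                                    endpoint = "renal", tier = "base",
                                    placebo_only = TRUE) {
  protein_ids <- protein_ids %||% attr(trial, "protein_ids")
  d <- trial
  if (placebo_only && "arm" %in% names(d)) d <- d %>% filter(.data$arm == 0)
  d$age_sex <- d$age * d$sex
  d$time <- d[[paste0("time_", endpoint)]]
  d$event <- d[[paste0("event_", endpoint)]]
  covs <- tier_covariates(endpoint, tier)

  purrr::map_dfr(protein_ids, function(pid) {
    t0 <- paste0(pid, "_t0")
    t1 <- paste0(pid, "_t1")
    if (!t1 %in% names(d)) {
      return(cox_fit(d, t0, covs) %>%
               mutate(protein_id = pid, mode = "baseline", .before = 1))
    }
    bind_rows(
      cox_fit(d, t0, covs) %>% mutate(mode = "baseline"),
      cox_fit(d, t1, covs) %>% mutate(mode = "repeat"),
      cox_fit(d, t1, c(covs, t0)) %>% mutate(mode = "repeat_adjusted")
    ) %>% mutate(protein_id = pid, .before = 1)
  })
}

#' PGS-to-outcome mediation through proteins in a trial
#'
#' Gate: the PGS must associate with the endpoint (Cox Wald p) and with
#' the candidate protein (linear model p), both at `gate_alpha`. For
#' qualifying proteins, natural-effects mediation ([mediate_binary()])
#' is run with the event indicator as the outcome and the treatment arm
#' added to the covariates, and BH FDR is applied to the indirect
#' p-values.
#'
#' @param trial trial table including a PGS column.
#' @param pgs_col name of the PGS column.
#' @param protein_ids candidate protein base names.
#' @param endpoint endpoint name.
#' @param gate_alpha gating threshold.
#' @param n_boot,seed bootstrap controls for the mediation.
#' @return tibble of mediation rows with `protein_id` and `indirect_q`;
#'   zero rows with attribute `gate_reason` when the gate closes.
#' @export
pgs_trial_mediation <- function(trial, pgs_col, protein_ids = NULL,
                                endpoint = "mace", gate_alpha = 0.05,
                                n_boot = 200, seed = 1) {
  protein_ids <- protein_ids %||% attr(trial, "protein_ids")
  d <- trial
  d$age_sex <- d$age * d$sex
  d$time <- d[[paste0("time_", endpoint)]]
  d$event <- d[[paste0("event_", endpoint)]]
  covs <- c("age", "sex", "age_sex", paste0("pc", 1:10), "arm")

  empty <- function(reason) {
    out <- tibble(protein_id = character())
    attr(out, "gate_reason") <- reason
    out
  }
  pgs_fit <- tryCatch(cox_fit(d, pgs_col, covs), error = function(e) NULL)
  if (is.null(pgs_fit) || pgs_fit$wald_p >= gate_alpha) {
    return(empty("PGS not associated with the endpoint"))
  }

  cov_df <- d[, covs, drop = FALSE]
  rows <- purrr::map_dfr(protein_ids, function(pid) {
    pcol <- paste0(pid, "_t0")
    pa <- linear_assoc(d[[pcol]], standardize(d[[pgs_col]]), cov_df)
    if (pa$pval >= gate_alpha) return(NULL)
    med <- mediate_binary(
      d %>% mutate(.pgs = standardize(.data[[pgs_col]])),
      exposure = ".pgs", mediator = pcol, outcome = "event",
      covariates = covs, n_boot = n_boot, seed = seed
    )
    med %>% mutate(protein_id = pid, .before = 1)
  })
  if (nrow(rows) == 0) return(empty("PGS not associated with any protein"))
  rows %>% mutate(indirect_q = bh_fdr(.data$p_indirect))
}
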