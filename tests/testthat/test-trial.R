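test_that("the Cox estimate agrees with a 1-D partial-likelihood grid search", {
  # tie-free 4-subject toy with a finite maximizer
  rec <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 1, 0),
                    x = c(1, 0, 1, 0))
  fit <- cox_fit(rec, "x")
  # Efron = Breslow here (no ties): brute-force the log partial likelihood
  logpl <- function(b) {
    risk <- exp(b * rec$x)
    sets <- list(1:4, 2:4, 3:4)
    ev <- c(1, 2, 3)
    sum(b * rec$x[ev] - vapply(seq_along(ev), function(i)
      log(sum(risk[sets[[i]]])), numeric(1)))
  }
  grid <- seq(-5, 5, by = 1e-4)
  b_grid <- grid[which.max(vapply(grid, logpl, numeric(1)))]
  expect_equal(fit$estimate, b_grid, tolerance = 1e-3)
  opt <- optimize(logpl, c(-5, 5), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(fit$estimate, opt, tolerance = 1e-6)

  # CI bounds reproduce exp(est -/+ 1.96 se)
  expect_equal(fit$ci_low, exp(fit$estimate - qnorm(0.975) * fit$se),
               tolerance = 1e-10)
  expect_equal(fit$ci_high, exp(fit$estimate + qnorm(0.975) * fit$se),
               tolerance = 1e-10)
})

test_that("tie methods agree on tie-free data and time units do not matter", {
  set.seed(70)
  n <- 300
  x <- rnorm(n)
  t_ev <- rexp(n, rate = 0.1 * exp(0.4 * x))
  cens <- rexp(n, 0.05)
  rec <- data.frame(time = pmin(t_ev, cens), event = as.integer(t_ev <= cens),
                    x = x)
  efron <- cox_fit(rec, "x", tie_method = "efron")
  breslow <- cox_fit(rec, "x", tie_method = "breslow")
  expect_equal(efron$estimate, breslow$estimate, tolerance = 1e-8)

  rec_days <- transform(rec, time = time * 365.25)
  expect_equal(cox_fit(rec_days, "x")$estimate, efron$estimate,
               tolerance = 1e-10)

  rec$const <- 1
  expect_error(cox_fit(rec, "x", covariates = "const"), "degenerate.*const")
  expect_error(cox_fit(transform(rec, event = 0), "x"), "no events")
})

test_that("the PH diagnostic flags time-varying effects and not proportional ones", {
  set.seed(71)
  flags <- vapply(1:30, function(s) {
    n <- 400
    x <- rnorm(n)
    # effect reverses sign halfway through follow-up
    t1 <- rexp(n, 0.2 * exp(0.8 * x))
    t2 <- 5 + rexp(n, 0.2 * exp(-0.8 * x))
    tt <- ifelse(t1 <= 5, t1, t2)
    rec <- data.frame(time = pmin(tt, 10), event = as.integer(tt <= 10), x = x)
    fit <- cox_fit(rec, "x")
    isTRUE(ph_test(fit)$global_p < 0.05)
  }, logical(1))
  expect_gte(mean(flags), 0.8)

  # single covariate: the global test is the per-term test
  set.seed(72)
  rec <- data.frame(time = rexp(200), event = 1L, x = rnorm(200))
  pt_ <- ph_test(cox_fit(rec, "x"))
  term_p <- pt_$table$p[pt_$table$term == "x"]
  expect_equal(pt_$global_p, term_p, tolerance = 1e-10)

  # fewer than 3 events: skipped with a reason
  tiny <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0),
                     x = c(0.1, -0.2, 0.3, 0.5))
  sk <- ph_test(cox_fit(tiny, "x"))
  expect_null(sk$table)
  expect_match(sk$skip_reason, "fewer than 3")
})

test_that("endpoint scanning recovers planted trial effects and honours tiers", {
  cfg <- sim_config(n_discovery = 10, n_replication = 2500,
                    n_gwas_exposure = 10, n_gwas_outcome = 10,
                    n_proteins = 10, n_pgs_targets = 2, n_causal_proteins = 3,
                    n_coloc_distinct = 1, pgs_n_variants = 10,
                    trial_log_hr = 0.5, n_trial_causal = 3, seed = 73)
  sim <- simulate_cohort(cfg, simulate_genotypes(cfg))
  trial <- simulate_trial(cfg, sim$cohort[sim$cohort$stratum == "replication", ],
                          sim$truth)
  disc <- endpoint_scan(trial, endpoints = "mace", tier = "base",
                        role = "discovery", placebo_only = FALSE)
  truth_trial <- sim$truth$proteins$protein_id[
    sim$truth$proteins$trial_log_hr != 0]
  found <- disc$protein_id[disc$significant]
  expect_gte(length(intersect(found, truth_trial)), 2)

  # replication restricts exactly to the discovery-hit set
  hits <- disc %>% dplyr::filter(significant)
  repl <- endpoint_scan(trial, endpoints = "mace", tier = "base",
                        role = "replication", discovery_hits = hits,
                        placebo_only = FALSE)
  expect_setequal(repl$protein_id, hits$protein_id)

  # the eGFR-proxy protein loses its association at the clinical tier
  conf <- attr(trial, "confounded_protein")
  base_conf <- endpoint_scan(trial, protein_ids = conf, endpoints = "hhf",
                             tier = "base", placebo_only = FALSE)
  clin_conf <- endpoint_scan(trial, protein_ids = conf, endpoints = "hhf",
                             tier = "clinical", placebo_only = FALSE)
  expect_lt(base_conf$wald_p, 0.05)
  expect_gt(clin_conf$wald_p, base_conf$wald_p)
  expect_lt(abs(clin_conf$estimate), abs(base_conf$estimate))
})

test_that("repeat-measurement modes expose reverse-causation inflation", {
  cfg <- sim_config(n_discovery = 10, n_replication = 1500,
                    n_gwas_exposure = 10, n_gwas_outcome = 10,
                    n_proteins = 8, n_pgs_targets = 2, n_causal_proteins = 2,
                    n_coloc_distinct = 1, pgs_n_variants = 10,
                    trial_log_hr = 0.4, n_trial_causal = 2,
                    test_retest_r = 0.5, seed = 74)
  sim <- simulate_cohort(cfg, simulate_genotypes(cfg))
  co <- sim$cohort[sim$cohort$stratum == "replication", ]

  inflated <- vapply(1:12, function(s) {
    cfg$seed <- 5000L + s
    tr <- simulate_trial(cfg, co, sim$truth, reverse_causation = TRUE,
                         confounded_protein = FALSE)
    modes <- repeat_measurement_scan(tr, protein_ids = "protein_01",
                                     endpoint = "renal", placebo_only = FALSE)
    est <- setNames(modes$estimate, modes$mode)
    c(repeat_gt_baseline = unname(est["repeat"] > est["baseline"]),
      adjusted_attenuates = unname(est["repeat_adjusted"] < est["repeat"]))
  }, logical(2))
  expect_gte(mean(inflated["repeat_gt_baseline", ]), 0.8)
  # baseline adjustment ameliorates the inflation on average
  expect_gt(mean(inflated["adjusted_attenuates", ]), 0.5)

  # perfect test-retest: baseline and repeat fits coincide
  cfg2 <- sim_config(n_discovery = 10, n_replication = 800,
                     n_gwas_exposure = 10, n_gwas_outcome = 10,
                     n_proteins = 8, n_pgs_targets = 2, n_causal_proteins = 2,
                     n_coloc_distinct = 1, pgs_n_variants = 10,
                     test_retest_r = 1, seed = 75)
  tr2 <- simulate_trial(cfg2, co[1:800, ], sim$truth,
                        confounded_protein = FALSE)
  m2 <- repeat_measurement_scan(tr2, protein_ids = "protein_02",
                                endpoint = "mace", placebo_only = FALSE)
  expect_equal(m2$estimate[m2$mode == "baseline"],
               m2$estimate[m2$mode == "repeat"], tolerance = 1e-8)
})

test_that("PGS-to-event trial mediation gates and detects a strong chain", {
  set.seed(76)
  n <- 3000
  pgs <- rnorm(n)
  prot <- 0.5 * pgs + rnorm(n, 0, sqrt(0.75))
  lp <- 0.8 * prot
  t_ev <- rexp(n, 0.05 * exp(lp))
  trial <- tibble::tibble(
    sample_id = sprintf("T%04d", 1:n), arm = rbinom(n, 1, 0.5),
    age = rnorm(n, 60, 8), sex = rbinom(n, 1, 0.5))
  for (p in paste0("pc", 1:10)) trial[[p]] <- rnorm(n)
  trial$pgs <- pgs
  trial$protein_a_t0 <- prot
  trial$protein_b_t0 <- rnorm(n)
  trial$time_mace <- pmin(t_ev, 5)
  trial$event_mace <- as.integer(t_ev <= 5)
  attr(trial, "protein_ids") <- c("protein_a", "protein_b")

  med <- pgs_trial_mediation(trial, "pgs", endpoint = "mace",
                             n_boot = 120, seed = 1)
  expect_true("protein_a" %in% med$protein_id)
  row_a <- med[med$protein_id == "protein_a", ]
  expect_lt(row_a$indirect_q, 0.05)

  # gate closes when the PGS is unrelated to the endpoint
  trial2 <- trial
  trial2$pgs <- rnorm(n)
  med2 <- pgs_trial_mediation(trial2, "pgs", endpoint = "mace",
                              n_boot = 120, seed = 1)
  expect_equal(nrow(med2), 0)
  expect_match(attr(med2, "gate_reason"), "endpoint")
})
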