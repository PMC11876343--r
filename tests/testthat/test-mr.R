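noise_free <- function(k = 0.3, j = 5) {
  bx <- seq(0.2, 0.6, length.out = j) * rep_len(c(1, -1), j)
  tibble::tibble(
    variant_id = paste0("v", seq_len(j)), effect_allele = "A",
    other_allele = "G", eaf_exposure = 0.3, eaf_outcome = 0.3,
    beta_exposure = bx, se_exposure = 0.03,
    beta_outcome = k * bx, se_outcome = 0.05,
    f_stat = (bx / 0.03)^2
  )
}

test_that("harmonization aligns alleles, flips swaps, and drops ambiguous palindromes", {
  mk_ss <- function(ea, oa, beta, eaf) {
    tibble::tibble(variant_id = "v1", chrom = 1L, pos = 100L,
                   effect_allele = ea, other_allele = oa, eaf = eaf,
                   beta = beta, se = 0.05, pval = 1e-10, n = 1000L,
                   trait_type = "quant", case_prop = NA_real_)
  }
  same <- harmonize(mk_ss("A", "G", 0.4, 0.3), mk_ss("A", "G", 0.2, 0.3))
  expect_equal(same$beta_outcome, 0.2)
  sw <- harmonize(mk_ss("A", "G", 0.4, 0.3), mk_ss("G", "A", 0.2, 0.7))
  expect_equal(sw$beta_outcome, -0.2)
  expect_equal(sw$eaf_outcome, 0.3)
  expect_equal(sw$f_stat, (0.4 / 0.05)^2, tolerance = 1e-10)
  # palindromic A/T with eaf 0.5 on both sides: uninformative, dropped
  amb <- harmonize(mk_ss("A", "T", 0.4, 0.5), mk_ss("A", "T", 0.2, 0.5))
  expect_equal(nrow(amb), 0)
  expect_equal(attr(amb, "n_dropped"), 1L)
  # palindrome with informative frequency on opposite sides is flipped
  pal <- harmonize(mk_ss("A", "T", 0.4, 0.2), mk_ss("A", "T", 0.2, 0.8))
  expect_equal(pal$beta_outcome, -0.2)
  expect_error(harmonize(mk_ss("A", "G", 0.4, 0.3)[0, ],
                         mk_ss("A", "G", 0.2, 0.3)), "no shared variants")
})

test_that("instrument QC applies the F, pleiotropy, and minimum-cis gates", {
  iv <- noise_free(j = 5)
  iv$beta_exposure[1] <- 0.1
  iv$se_exposure[1] <- 0.04
  iv$f_stat <- (iv$beta_exposure / iv$se_exposure)^2
  expect_equal(iv$f_stat[1], 6.25)
  iv$n_proteins_hit <- c(0, 5, 4, 0, 0)
  iv$is_cis <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  out <- instrument_qc(iv, cis_only = TRUE)
  # v1 weak (F 6.25), v2 hits 5 proteins, v5 trans: v3 (4 hits) and v4 stay
  expect_setequal(out$variant_id, c("v3", "v4"))
  expect_true(attr(out, "skip"))
  expect_match(attr(out, "skip_reason"), "2 cis instrument")
  out2 <- instrument_qc(iv, cis_only = FALSE)
  expect_setequal(out2$variant_id, c("v3", "v4", "v5"))
  expect_false(attr(out2, "skip"))
})

test_that("IVW equals the weighted-least-squares-through-origin oracle", {
  set.seed(40)
  iv <- simulate_mr_instruments(5, true_effect = 0.4, seed = 41)
  got <- ivw(iv)
  # independent oracle: WLS through the origin with weights 1/se_y^2
  w <- 1 / iv$se_outcome^2
  num <- sum(w * iv$beta_exposure * iv$beta_outcome)
  den <- sum(w * iv$beta_exposure^2)
  expect_equal(got$estimate, num / den, tolerance = 1e-12)
  expect_equal(got$se, sqrt(1 / den), tolerance = 1e-12)
  oracle_fit <- lm(beta_outcome ~ 0 + beta_exposure, data = iv, weights = w)
  expect_equal(got$estimate, unname(coef(oracle_fit)), tolerance = 1e-12)

  # single instrument: Wald ratio
  w1 <- ivw(iv[1, ])
  expect_equal(w1$method, "wald")
  expect_equal(w1$estimate, iv$beta_outcome[1] / iv$beta_exposure[1])
  expect_equal(w1$se, iv$se_outcome[1] / abs(iv$beta_exposure[1]))

  # exact proportionality: estimate k, Q = 0
  prop <- ivw(noise_free(0.5))
  expect_equal(prop$estimate, 0.5, tolerance = 1e-12)
  expect_equal(prop$cochran_q, 0, tolerance = 1e-12)
})

test_that("median estimators follow the cumulative-weight interpolation rule", {
  iv <- noise_free(j = 5)
  iv$beta_outcome <- iv$beta_exposure * c(0.1, 0.3, 0.5, 0.7, 0.9)
  sm <- median_mr(iv, weighted = FALSE, n_boot = 200, seed = 1)
  expect_equal(sm$estimate, 0.5, tolerance = 1e-12)  # middle order statistic

  # dominant-weight toy: ratios (0.2, 0.5, 0.9), weights (1, 10, 1)
  ivw3 <- tibble::tibble(
    variant_id = c("a", "b", "c"), effect_allele = "A", other_allele = "G",
    eaf_exposure = 0.3, eaf_outcome = 0.3,
    beta_exposure = c(1, sqrt(10), 1), se_exposure = 0.01,
    beta_outcome = c(0.2, 0.5 * sqrt(10), 0.9), se_outcome = 1,
    f_stat = 1e6)
  wm <- median_mr(ivw3, weighted = TRUE, n_boot = 200, seed = 1)
  expect_equal(wm$estimate, 0.5, tolerance = 1e-12)

  # identical ratios: estimate k with a small bootstrap SE
  ident <- median_mr(noise_free(0.3), weighted = TRUE, n_boot = 200, seed = 2)
  expect_equal(ident$estimate, 0.3, tolerance = 1e-12)
  expect_lt(ident$se, 0.1)
  expect_error(median_mr(noise_free(0.3)[1:2, ]), ">= 3 instruments")
})

test_that("Egger regression separates slope from directional pleiotropy", {
  clean <- egger(noise_free(0.3, j = 6))
  expect_equal(clean$estimate[clean$method == "egger_slope"], 0.3,
               tolerance = 1e-10)
  expect_equal(clean$estimate[clean$method == "egger_intercept"], 0,
               tolerance = 1e-10)

  # constant shift on every oriented outcome beta moves only the intercept
  iv <- noise_free(0.3, j = 6)
  shifted <- iv
  shifted$beta_outcome <- shifted$beta_outcome + 0.1 * sign(shifted$beta_exposure)
  sh <- egger(shifted)
  expect_equal(sh$estimate[sh$method == "egger_intercept"], 0.1,
               tolerance = 1e-10)
  expect_equal(sh$estimate[sh$method == "egger_slope"], 0.3, tolerance = 1e-10)
})

test_that("all estimators return exactly k on noise-free proportional data", {
  fits <- mr_all(noise_free(0.42, j = 7), n_boot = 100, seed = 3)
  est <- fits$estimate[fits$method %in%
                         c("ivw", "simple_median", "weighted_median",
                           "egger_slope")]
  expect_equal(est, rep(0.42, 4), tolerance = 1e-10)

  # invariance under joint allele relabelling (both betas negated)
  iv <- simulate_mr_instruments(10, 0.3, seed = 44)
  flip <- iv
  flip$beta_exposure <- -flip$beta_exposure
  flip$beta_outcome <- -flip$beta_outcome
  f1 <- mr_all(iv, n_boot = 100, seed = 5)
  f2 <- mr_all(flip, n_boot = 100, seed = 5)
  expect_equal(f1$estimate[f1$method == "ivw"],
               f2$estimate[f2$method == "ivw"], tolerance = 1e-12)
  expect_equal(f1$estimate[f1$method == "egger_slope"],
               f2$estimate[f2$method == "egger_slope"], tolerance = 1e-10)
})

test_that("consensus takes the median p, flags pleiotropy, and gates significance", {
  mk_fits <- function(pid, p4, p_int) {
    tibble::tibble(
      protein_id = pid,
      method = c("ivw", "simple_median", "weighted_median", "egger_slope",
                 "egger_intercept"),
      estimate = 0.3, se = 0.1, pval = c(p4, p_int),
      n_instruments = 5L, cochran_q = NA_real_, q_pval = NA_real_)
  }
  fits <- dplyr::bind_rows(
    mk_fits("pA", c(0.001, 0.002, 0.03, 0.7), 0.5),
    mk_fits("pB", c(1e-6, 1e-5, 1e-5, 1e-4), 0.01),  # pleiotropic
    mk_fits("pC", c(0.5, 0.5, 0.5, 0.5), 0.9))
  cons <- consensus(fits, alpha = 0.05)
  expect_equal(cons$median_p[cons$protein_id == "pA"], mean(c(0.002, 0.03)))
  expect_equal(cons$median_p[cons$protein_id == "pC"], 0.5)
  expect_true(cons$pleiotropy_flag[cons$protein_id == "pB"])
  expect_false(cons$significant[cons$protein_id == "pB"])
  expect_equal(attr(cons, "bonferroni_threshold"), 0.05 / (3 * 4))
})

test_that("MVMR reduces to IVW, recovers dual effects, and detects collinearity", {
  iv <- simulate_mr_instruments(20, 0.3, seed = 50)
  tab <- tibble::tibble(
    beta_exposure1 = iv$beta_exposure, se_exposure1 = iv$se_exposure,
    beta_exposure2 = 0, se_exposure2 = 0.02,
    beta_outcome = iv$beta_outcome, se_outcome = iv$se_outcome)
  red <- mvmr(tab)
  expect_equal(red$estimates$estimate[1], ivw(iv)$estimate, tolerance = 1e-10)
  expect_false(red$retained)

  rec <- mvmr(simulate_mvmr_instruments(50, 0.3, 0.2, seed = 51),
              exposure_names = c("protein", "bmi"))
  expect_lt(abs(rec$estimates$estimate[1] - 0.3), 0.05)
  expect_lt(abs(rec$estimates$estimate[2] - 0.2), 0.05)
  expect_true(all(rec$estimates$conditional_f > 10))

  coll <- simulate_mvmr_instruments(20, 0.3, 0.2, seed = 52)
  coll$beta_exposure2 <- 2 * coll$beta_exposure1
  expect_error(mvmr(coll), "singular|collinear")
  expect_error(mvmr(simulate_mvmr_instruments(2, seed = 1)), ">= 3 instruments")
})

test_that("reverse MR skips cleanly when the trait has no significant variants", {
  sim <- small_sim()
  null_trait <- compute_summary_stats(
    subset_samples(sim$genotypes, 1:500),
    rnorm(500), trait_type = "quant",
    variant_ids = sim$genotypes$variants$variant_id[1:30])
  out <- reverse_mr(null_trait, list(protein_01 = null_trait),
                    sim$genotypes)
  expect_null(out$consensus)
  expect_match(out$skip_reason, "no genome-wide-significant")
})

test_that("fixed-effect meta-analysis pools strata by inverse variance", {
  sim <- small_sim()
  i1 <- which(sim$cohort$stratum == "discovery")
  i2 <- which(sim$cohort$stratum == "replication")
  vids <- sim$genotypes$variants$variant_id[1:10]
  s1 <- compute_summary_stats(subset_samples(sim$genotypes, i1),
                              sim$cohort$protein_01[i1],
                              trait_type = "quant", variant_ids = vids)
  s2 <- compute_summary_stats(subset_samples(sim$genotypes, i2),
                              sim$cohort$protein_01[i2],
                              trait_type = "quant", variant_ids = vids)
  meta <- meta_sumstats(list(a = s1, b = s2))
  j <- match(vids[1], meta$variant_id)
  w1 <- 1 / s1$se[1]^2
  w2 <- 1 / s2$se[1]^2
  expect_equal(meta$beta[j], (s1$beta[1] * w1 + s2$beta[1] * w2) / (w1 + w2),
               tolerance = 1e-12)
  expect_equal(meta$se[j], sqrt(1 / (w1 + w2)), tolerance = 1e-12)
  expect_true(all(meta$se < pmin(s1$se, s2$se)[match(meta$variant_id, vids)]))
})
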