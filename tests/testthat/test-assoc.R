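test_that("linear association matches the normal-equations oracle", {
  # hand-written 10-row design
  y <- c(2.1, 1.4, 3.3, 0.2, 1.9, 2.8, 0.7, 1.1, 2.4, 3.0)
  x <- c(1.0, 0.5, 2.0, -1., 0.8, 1.7, -.5, 0.1, 1.2, 1.9)
  c1 <- c(0.3, -1., 0.5, 0.2, 1.1, -.7, 0.9, -.2, 0.4, 0.6)
  got <- linear_assoc(y, x, data.frame(c1 = c1))

  X <- cbind(1, c1, x)
  bh <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% bh
  s2 <- sum(res^2) / (10 - 3)
  V <- s2 * solve(t(X) %*% X)
  expect_equal(got$beta, unname(bh[3, 1]), tolerance = 1e-10)
  expect_equal(got$se, sqrt(V[3, 3]), tolerance = 1e-10)
  expect_equal(got$pval, unname(2 * pt(-abs(bh[3, 1] / sqrt(V[3, 3])), 7)),
               tolerance = 1e-10)

  # identity: y = x, no covariates
  id <- linear_assoc(x, x)
  expect_equal(id$beta, 1, tolerance = 1e-12)
  expect_gt(id$r2_partial, 0.999)

  # collinearity names the aliased column
  expect_error(linear_assoc(y, x, data.frame(c1 = c1, c2 = 2 * c1)),
               "collinear.*c2")
})

test_that("null association p-values are calibrated", {
  set.seed(12)
  p <- vapply(1:500, function(i) linear_assoc(rnorm(60), rnorm(60))$pval,
              numeric(1))
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.08)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(1, 1, 1)), c(1, 1, 1))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), bh_bruteforce(p), tolerance = 1e-12)
  }
})

test_that("Bonferroni discovery thresholds reproduce the study-scale rules", {
  expect_equal(signif(bonferroni_threshold(0.05, 10, 2922), 2), 1.7e-6)
  expect_equal(bonferroni_threshold(0.05, 2, 5), 0.005)
  expect_equal(signif(bonferroni_threshold(0.05, 2922, 4), 2), 4.3e-6)
})

test_that("prevalent-disease filtering removes exactly the flagged rows", {
  co <- tibble::tibble(sample_id = paste0("S", 1:6),
                       prevalent_disease = c(0, 1, 0, 0, 1, 0))
  out <- filter_prevalent(co)
  expect_equal(out$sample_id, paste0("S", c(1, 3, 4, 6)))
  expect_equal(attr(out, "n_removed"), 2L)
  expect_equal(nrow(filter_prevalent(co[co$prevalent_disease == 0, ])), 4)
  all_flagged <- filter_prevalent(co[co$prevalent_disease == 1, ])
  expect_equal(nrow(all_flagged), 0)
  expect_error(run_scan(all_flagged, tibble::tibble(sample_id = character())),
               "empty cohort")
})

test_that("two-stage scan recovers planted targets against the truth ledger", {
  hits_by_seed <- vapply(c(301, 302, 303), function(s) {
    cfg <- small_config(seed = s)
    g <- simulate_genotypes(cfg)
    sim <- simulate_cohort(cfg, g)
    cohort <- filter_prevalent(sim$cohort)
    sc <- compute_pgs(g, truth_weightset(sim$truth),
                      reference = which(sim$cohort$stratum == "discovery"))
    scores <- tibble::tibble(sample_id = sc$sample_id, pgs_gw = sc$score_std)
    rep_set <- run_scan(cohort, scores)$replication
    truth_targets <- sim$truth$proteins$protein_id[
      sim$truth$proteins$pgs_total != 0]
    found <- rep_set$protein_id[rep_set$replicated]
    c(recovered = length(intersect(found, truth_targets)) /
        length(truth_targets),
      false_pos = length(setdiff(found, truth_targets)))
  }, numeric(2))
  expect_true(all(hits_by_seed["recovered", ] == 1))
  expect_true(all(hits_by_seed["false_pos", ] <= 1))
})

test_that("adjustment classification separates pQTL-channelled from polygenic effects", {
  set.seed(14)
  n <- 4000
  dos <- rbinom(n, 2, 0.3)
  dstd <- (dos - mean(dos)) / sd(dos)
  # the score's effect on protein_channel flows entirely through this pQTL
  pgs <- 0.7 * dstd + sqrt(1 - 0.49) * rnorm(n)
  poly <- rnorm(n)  # purely polygenic score
  cohort <- tibble::tibble(
    sample_id = sprintf("S%04d", 1:n),
    stratum = rep(c("discovery", "replication"), each = n / 2),
    age = rnorm(n, 58, 8), sex = rbinom(n, 1, 0.5),
    prevalent_disease = 0L
  )
  for (p in paste0("pc", 1:10)) cohort[[p]] <- rnorm(n)
  cohort$protein_channel <- 0.4 * dstd + rnorm(n, 0, 0.9)
  cohort$protein_poly <- 0.4 * poly + rnorm(n, 0, 0.9)
  scores <- tibble::tibble(sample_id = cohort$sample_id,
                           s_chan = pgs, s_poly = poly)
  pqtl_cov <- tibble::tibble(sample_id = cohort$sample_id, pqtl1 = dos)
  out <- adjusted_scan(cohort, scores,
                       protein_ids = c("protein_channel", "protein_poly"),
                       extra = pqtl_cov)
  cls <- out$classification
  expect_equal(cls$status[cls$score_id == "s_chan" &
                            cls$protein_id == "protein_channel"],
               "attenuated_to_nonsignificance")
  expect_equal(cls$status[cls$score_id == "s_poly" &
                            cls$protein_id == "protein_poly"],
               "still_significant")
})

test_that("beta comparison handles self, sign-flip, and sparse input", {
  a <- tibble::tibble(protein_id = paste0("p", 1:20),
                      beta = rnorm(20), pval = runif(20))
  self <- compare_betas(a, a)
  expect_equal(self$pearson_r, 1, tolerance = 1e-12)
  expect_equal(self$slope, 1, tolerance = 1e-12)
  flip <- compare_betas(a, a %>% dplyr::mutate(beta = -beta))
  expect_equal(flip$pearson_r, -1, tolerance = 1e-12)
  expect_error(compare_betas(a[1:2, ], a[1:2, ]), "fewer than 3")
})

test_that("stronger-stratum betas correlate more tightly among significant pairs", {
  # winner's-curse-free property: with identical truth at different n,
  # restricting to significant pairs cannot degrade the correlation much
  set.seed(15)
  wins <- vapply(1:25, function(i) {
    truth <- rnorm(40, 0, 0.3)
    a <- tibble::tibble(protein_id = paste0("p", 1:40),
                        beta = truth + rnorm(40, 0, 0.05))
    a$pval <- 2 * pnorm(-abs(a$beta / 0.05))
    b <- tibble::tibble(protein_id = a$protein_id,
                        beta = truth + rnorm(40, 0, 0.15), pval = 1)
    r_all <- compare_betas(a, b, "all")$pearson_r
    r_sig <- tryCatch(
      compare_betas(a, b, "significant_only", sig_threshold = 1e-4)$pearson_r,
      error = function(e) NA_real_)
    isTRUE(r_sig >= r_all - 0.05)
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})
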