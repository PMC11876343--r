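toy3 <- function() {
  dos <- matrix(c(0, 1, 2,
                  2, 1, 0,
                  1, 1, 1), ncol = 3,
                dimnames = list(NULL, c("rs1", "rs2", "rs3")))
  toy_genotypes(dos)
}

test_that("scoring identities: null weights, single variant, allele flip", {
  g <- toy3()
  w0 <- tibble::tibble(variant_id = c("rs1", "rs2"), effect_allele = "A",
                       other_allele = "G", weight = 0, score_id = "s")
  expect_equal(compute_pgs(g, w0)$score, c(0, 0, 0))

  w1 <- tibble::tibble(variant_id = "rs1", effect_allele = "A",
                       other_allele = "G", weight = 1, score_id = "s")
  expect_equal(compute_pgs(g, w1)$score, as.numeric(g$dosages[, "rs1"]))

  # weight's effect allele is the matrix's OTHER allele: score = 2 - dosage
  wf <- tibble::tibble(variant_id = "rs1", effect_allele = "G",
                       other_allele = "A", weight = 1, score_id = "s")
  expect_equal(compute_pgs(g, wf)$score, 2 - as.numeric(g$dosages[, "rs1"]))
})

test_that("scoring is order-invariant and obeys the complement identity", {
  sim <- small_sim()
  w <- truth_weightset(sim$truth)
  s1 <- compute_pgs(sim$genotypes, w)
  s2 <- compute_pgs(sim$genotypes, w[rev(seq_len(nrow(w))), ])
  expect_equal(s1$score, s2$score, tolerance = 1e-12)

  # flipping every effect/other allele: new = 2 * sum(w) - old
  wflip <- w
  wflip$effect_allele <- w$other_allele
  wflip$other_allele <- w$effect_allele
  s3 <- compute_pgs(sim$genotypes, wflip)
  expect_equal(s3$score, 2 * sum(w$weight) - s1$score, tolerance = 1e-10)

  # standardization invariant in the reference stratum
  ref <- which(sim$cohort$stratum == "discovery")
  s4 <- compute_pgs(sim$genotypes, w, reference = ref)
  expect_lt(abs(mean(s4$score_std[ref])), 1e-10)
  expect_lt(abs(sd(s4$score_std[ref]) - 1), 1e-10)
})

test_that("missing and irreconcilable variants follow the stated policies", {
  g <- toy3()
  w <- tibble::tibble(variant_id = c("rs1", "rs_absent"),
                      effect_allele = "A", other_allele = "G",
                      weight = c(1, 5), eaf = c(0.3, 0.25), score_id = "s")
  s_drop <- compute_pgs(g, w, missing_policy = "drop")
  expect_equal(s_drop$score, as.numeric(g$dosages[, "rs1"]))
  expect_equal(attr(s_drop, "n_missing"), 1L)
  s_imp <- compute_pgs(g, w, missing_policy = "mean_impute")
  expect_equal(s_imp$score, as.numeric(g$dosages[, "rs1"]) + 5 * 2 * 0.25)

  w_bad <- tibble::tibble(variant_id = c("rs1", "rs2"),
                          effect_allele = c("A", "C"),
                          other_allele = c("G", "T"),
                          weight = 1, score_id = "s")
  expect_warning(s_bad <- compute_pgs(g, w_bad), "irreconcilable")
  expect_equal(attr(s_bad, "n_allele_dropped"), 1L)

  w_none <- tibble::tibble(variant_id = "nope", effect_allele = "A",
                           other_allele = "G", weight = 1, score_id = "s")
  expect_error(compute_pgs(g, w_none), "no overlap")
})

test_that("weight files round-trip with metadata comments", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# PGS metadata line", "# build: synthetic",
               "rsID\teffect_allele\tother_allele\teffect_weight",
               "rs1\tA\tG\t0.5", "rs2\tG\tA\t-0.25"), path)
  w <- read_pgs_weights(path, score_id = "toy")
  expect_equal(w$variant_id, c("rs1", "rs2"))
  expect_equal(w$weight, c(0.5, -0.25))
  g <- toy3()
  # rs2 enters flipped (its effect allele is the matrix's other allele)
  expect_equal(compute_pgs(g, w)$score,
               unname(0.5 * g$dosages[, "rs1"] +
                        (-0.25) * (2 - g$dosages[, "rs2"])))
})

test_that("clumping matches a brute-force greedy oracle on a constructed toy", {
  # 5 variants; LD blocks: v1-v2 highly correlated, v5 correlated with v3
  set.seed(42)
  base1 <- rbinom(400, 1, 0.4) + rbinom(400, 1, 0.4)
  base2 <- rbinom(400, 1, 0.3) + rbinom(400, 1, 0.3)
  flip <- function(x, p) ifelse(runif(400) < p, rbinom(400, 2, 0.4), x)
  dos <- cbind(v1 = base1, v2 = flip(base1, 0.05),
               v3 = base2, v4 = rbinom(400, 2, 0.5),
               v5 = flip(base2, 0.05))
  g <- toy_genotypes(dos, pos = c(1000L, 2000L, 3000L, 4000L, 500000L))
  ss <- tibble::tibble(
    variant_id = paste0("v", 1:5), chrom = 1L,
    pos = g$variants$pos, effect_allele = "A", other_allele = "G",
    eaf = colMeans(dos) / 2, beta = c(0.5, 0.4, 0.3, 0.1, 0.6),
    se = 0.05, pval = c(1e-10, 1e-9, 1e-8, 0.5, 1e-12),
    n = 400L, trait_type = "quant", case_prop = NA_real_)

  params <- clump_params(5e-8, 0.1, 250)
  got <- clump(ss, g, params)

  # independent greedy oracle by exhaustive rule evaluation
  r2 <- cor(dos)^2
  cand <- order(ss$pval)
  cand <- cand[ss$pval[cand] < params$p_threshold]
  claimed <- rep(FALSE, 5)
  keep <- integer(0)
  for (i in cand) {
    if (claimed[i]) next
    keep <- c(keep, i)
    claimed[i] <- TRUE
    for (k in cand) {
      if (!claimed[k] && abs(ss$pos[k] - ss$pos[i]) <= 250000 &&
            r2[i, k] > params$r2_threshold) claimed[k] <- TRUE
    }
  }
  expect_setequal(got$variant_id, paste0("v", sort(keep)))
  # v5 is 500 kb from v3 (outside the 250 kb window) so survives despite LD
  expect_true("v5" %in% got$variant_id)
  expect_false("v2" %in% got$variant_id)

  # row-order invariance
  got_rev <- clump(ss[5:1, ], g, params)
  expect_setequal(got_rev$variant_id, got$variant_id)

  # boundary cases
  expect_equal(nrow(clump(ss, g, clump_params(1e-20, 0.1, 250))), 0)
  all_kept <- clump(ss, g, clump_params(5e-8, 1.0, 250))
  expect_setequal(all_kept$variant_id, c("v1", "v2", "v3", "v5"))
})

test_that("score validation recovers identities and simulated effects", {
  set.seed(9)
  s <- rnorm(500)
  out <- validate_pgs(s, s)
  expect_equal(out$estimate, sd(s), tolerance = 1e-8)
  expect_lt(out$pval, 1e-200)
  expect_error(validate_pgs(s, rep(1, 500)), "constant")

  # logistic recovery of a true per-SD log-odds of 0.3
  set.seed(10)
  n <- 10000
  sc <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2 + 0.3 * sc))
  fit <- validate_pgs(sc, y)
  expect_equal(fit$model, "logistic")
  expect_lt(abs(fit$estimate - 0.3), 0.06)

  # type-I calibration under the null
  set.seed(11)
  p <- vapply(1:200, function(i) {
    validate_pgs(rnorm(300), rnorm(300))$pval
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.10)
})
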