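region_from_labf <- function(labf, ids = NULL, prior_sd = 0.15) {
  # invert the Wakefield formula at fixed se to get betas with these labfs
  se <- 0.05
  v <- se^2
  w <- prior_sd^2
  z2 <- (2 * labf - log(v / (v + w))) * (v + w) / w
  tibble::tibble(
    variant_id = ids %||% sprintf("v%02d", seq_along(labf)),
    chrom = 1L, pos = 1000L + seq_along(labf),
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = sqrt(pmax(0, z2)) * se, se = se,
    pval = 2 * pnorm(-sqrt(pmax(0, z2))), n = 1000L,
    trait_type = "quant", case_prop = NA_real_)
}

test_that("the Wakefield log ABF follows its closed form", {
  # V = W, z^2 = 2: labf = 0.5 * (ln(1/2) + 1) ~ 0.1534
  expect_equal(wakefield_labf(0.05 * sqrt(2), 0.05, 0.05),
               0.5 * (log(0.5) + 1), tolerance = 1e-12)
  expect_equal(round(wakefield_labf(0.05 * sqrt(2), 0.05, 0.05), 4), 0.1534)
  # null effect shrinks evidence
  expect_lt(wakefield_labf(0, 0.05, 0.2), 0)
  # point-null prior limit: labf -> 0 as W -> 0
  expect_lt(abs(wakefield_labf(0.1, 0.05, 1e-8)), 1e-5)
  expect_error(wakefield_labf(Inf, 0.05, 0.2), "finite")
})

test_that("posteriors match exhaustive two-trait configuration enumeration", {
  labf <- c(0, 2, 4)
  r1 <- region_from_labf(labf)
  r2 <- region_from_labf(labf)
  post <- coloc(r1, r2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5)

  # brute force over all single-variant configurations
  bf <- exp(labf)
  p1 <- 1e-4; p2 <- 1e-4; p12 <- 1e-5
  h0 <- 1
  h1 <- p1 * sum(bf)
  h2 <- p2 * sum(bf)
  h4 <- p12 * sum(bf * bf)
  h3 <- p1 * p2 * (sum(outer(bf, bf)) - sum(bf * bf))  # 9 - 3 configurations
  tot <- h0 + h1 + h2 + h3 + h4
  expect_equal(post$pp_h0, h0 / tot, tolerance = 1e-10)
  expect_equal(post$pp_h1, h1 / tot, tolerance = 1e-10)
  expect_equal(post$pp_h2, h2 / tot, tolerance = 1e-10)
  expect_equal(post$pp_h3, h3 / tot, tolerance = 1e-10)
  expect_equal(post$pp_h4, h4 / tot, tolerance = 1e-10)
})

test_that("posterior invariants: normalization, symmetry, inert variants", {
  set.seed(60)
  for (i in 1:10) {
    m <- sample(3:8, 1)
    r1 <- region_from_labf(runif(m, -1, 8))
    r2 <- region_from_labf(runif(m, -1, 8))
    post <- coloc(r1, r2)
    expect_equal(post$pp_h0 + post$pp_h1 + post$pp_h2 + post$pp_h3 + post$pp_h4,
                 1, tolerance = 1e-12)
    sw <- coloc(r2, r1)
    expect_equal(sw$pp_h4, post$pp_h4, tolerance = 1e-10)
    expect_equal(sw$pp_h1, post$pp_h2, tolerance = 1e-10)
    expect_equal(sw$pp_h2, post$pp_h1, tolerance = 1e-10)
  }

  # appending a no-evidence variant to both traits changes nothing material
  r1 <- region_from_labf(c(0, 2, 4))
  r2 <- region_from_labf(c(1, 3, 2))
  base <- coloc(r1, r2)
  # beta = 0 with a vanishing SE drives the log ABF towards -Inf
  inert <- region_from_labf(0, ids = "inert")
  inert$beta <- 0
  inert$se <- 1e-14
  expect_lt(wakefield_labf(0, 1e-14, 0.15), -25)
  aug <- coloc(dplyr::bind_rows(r1, inert), dplyr::bind_rows(r2, inert))
  for (h in paste0("pp_h", 0:4)) {
    expect_equal(aug[[h]], base[[h]], tolerance = 1e-10)
  }

  expect_error(coloc(r1[1, ], r2[1, ]), "insufficient overlap")
})

test_that("the decision rule applies the sum and ratio gates", {
  mk <- function(h0, h1, h2, h3, h4) {
    tibble::tibble(pp_h0 = h0, pp_h1 = h1, pp_h2 = h2, pp_h3 = h3, pp_h4 = h4)
  }
  expect_true(coloc_decision(mk(0, 0, 0, 0.1, 0.9)))    # sum 1, ratio 9
  expect_false(coloc_decision(mk(0, 0, 0, 0.5, 0.5)))   # ratio 1
  expect_true(coloc_decision(mk(0, 0, 0, 0, 1)))        # ratio +Inf
  expect_false(coloc_decision(mk(0.05, 0, 0, 0.05, 0.9)))  # sum 0.95
})

test_that("region selection seeds on double significance and merges overlaps", {
  mk_gwas <- function(pvals, pos) {
    tibble::tibble(variant_id = paste0("v", seq_along(pvals)), chrom = 1L,
                   pos = pos, effect_allele = "A", other_allele = "G",
                   eaf = 0.3, beta = 0.1, se = 0.05, pval = pvals,
                   n = 1000L, trait_type = "quant", case_prop = NA_real_)
  }
  none <- select_regions(mk_gwas(c(0.5, 0.2), c(1e6, 2e6)),
                         mk_gwas(c(0.5, 0.2), c(1e6, 2e6)))
  expect_equal(nrow(none), 0)

  one <- select_regions(mk_gwas(c(1e-8, 0.5), c(1000000L, 5000000L)),
                        mk_gwas(c(1e-8, 0.5), c(1000000L, 5000000L)))
  expect_equal(one$start, 750001L)
  expect_equal(one$end, 1250000L)

  # two seeds 100 kb apart merge into a single region
  two <- select_regions(mk_gwas(c(1e-8, 1e-8), c(1000000L, 1100000L)),
                        mk_gwas(c(1e-8, 1e-8), c(1000000L, 1100000L)))
  expect_equal(nrow(two), 1)
  expect_equal(two$n_seeds, 2L)
  expect_equal(two$start, 750001L)
  expect_equal(two$end, 1350000L)
})

test_that("generator scenarios produce the expected dominant hypothesis", {
  outcomes <- vapply(1:15, function(s) {
    sh <- simulate_coloc_pair("shared", n1 = 8000, n2 = 8000, seed = 700 + s)
    di <- simulate_coloc_pair("distinct", n1 = 8000, n2 = 8000, seed = 900 + s)
    nu <- simulate_coloc_pair("null", n1 = 2000, n2 = 2000, seed = 1100 + s)
    p_sh <- coloc(sh$region1, sh$region2)
    p_di <- coloc(di$region1, di$region2)
    p_nu <- coloc(nu$region1, nu$region2)
    c(shared_h4 = p_sh$pp_h4 > 0.9,
      distinct_h3 = p_di$pp_h3 > p_di$pp_h4,
      null_h0 = p_nu$pp_h0 > 0.9)
  }, logical(3))
  expect_gte(mean(outcomes["shared_h4", ]), 0.8)
  expect_gte(mean(outcomes["distinct_h3", ]), 0.8)
  expect_gte(mean(outcomes["null_h0", ]), 0.8)
})
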