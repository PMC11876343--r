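#' Simulate summary-level two-sample MR instruments
#'
#' Draws instrument-level effect estimates directly on the summary scale:
#' true per-allele exposure effects are uniform in magnitude on
#' `[bx_min, bx_max]` with alternating sign, observed exposure and outcome
#' betas add independent normal noise at the stated standard errors, and
#' the outcome truth is `true_effect * beta_x + pleiotropy_intercept`
#' (directional pleiotropy enters as a constant shift, balanced pleiotropy
#' as `pleiotropy_sd`). Used by the calibration and coverage analyses,
#' where thousands of replicates are needed.
#'
#' @param n_instruments number of instruments J.
#' @param true_effect causal effect of exposure on outcome.
#' @param bx_min,bx_max magnitude range of the true exposure effects.
#' @param se_exposure,se_outcome standard errors (recycled to length J).
#' @param pleiotropy_intercept constant added to every outcome beta.
#' @param pleiotropy_sd SD of balanced per-instrument pleiotropy.
#' @param seed optional integer seed.
#' @return an instrument tibble compatible with the MR fitters
#'   (`variant_id`, alleles, `eaf_*`, `beta_*`, `se_*`, `f_stat`).
#' @export
simulate_mr_instruments <- function(n_instruments = 20, true_effect = 0,
                                    bx_min = 0.2, bx_max = 0.5,
                                    se_exposure = 0.03, se_outcome = 0.05,
                                    pleiotropy_intercept = 0,
                                    pleiotropy_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  j <- n_instruments
  bx_true <- runif(j, bx_min, bx_max) * rep_len(c(1, -1), j)
  se_x <- rep_len(se_exposure, j)
  se_y <- rep_len(se_outcome, j)
  bx <- bx_true + rnorm(j, 0, se_x)
  by <- true_effect * bx_true + pleiotropy_intercept * sign(bx_true) +
    rnorm(j, 0, sqrt(se_y^2 + pleiotropy_sd^2))
  tibble(
    variant_id = sprintf("iv%03d", seq_len(j)),
    effect_allele = "A", other_allele = "G",
    eaf_exposure = 0.3, eaf_outcome = 0.3,
    beta_exposure = bx, se_exposure = se_x,
    beta_outcome = by, se_outcome = se_y,
    f_stat = (bx / se_x)^2
  )
}

#' Simulate a colocalization region pair with known scenario
#'
#' Generates two independent samples of one LD region and a quantitative
#' trait in each, then returns the per-variant summary statistics. Under
#' `"shared"` both traits are driven by the same causal variant; under
#' `"distinct"` by two well-separated variants; under `"null"` neither
#' trait has a signal.
#'
#' @param scenario `"shared"`, `"distinct"`, or `"null"`.
#' @param n1,n2 sample sizes of the two GWAS.
#' @param n_variants region size.
#' @param ld_rho adjacent-haplotype correlation.
#' @param maf region minor-allele frequency.
#' @param h2 variance explained by the causal variant in each trait.
#' @param seed optional integer seed.
#' @return list with `region1`, `region2` (`summary_stats` tibbles) and
#'   `causal` (the causal variant index per trait, `NA` under the null).
#' @export
simulate_coloc_pair <- function(scenario = c("shared", "distinct", "null"),
                                n1 = 10000, n2 = 10000, n_variants = 20,
                                ld_rho = 0.5, maf = 0.3, h2 = 0.01,
                                seed = NULL) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- n_variants
  c1 <- ceiling(m / 3)
  c2 <- if (scenario == "shared") c1 else m - ceiling(m / 3) + 1L
  if (scenario == "null") c1 <- c2 <- NA_integer_

  make_one <- function(n, causal) {
    dos <- sim_region_haplotypes(n, m, maf, ld_rho) +
      sim_region_haplotypes(n, m, maf, ld_rho)
    colnames(dos) <- sprintf("rv%02d", seq_len(m))
    y <- rnorm(n)
    if (!is.na(causal)) {
      b <- sqrt(h2 / (2 * maf * (1 - maf)))
      y <- y * sqrt(1 - h2) + b * (dos[, causal] - 2 * maf)
    }
    g <- structure(list(
      dosages = dos,
      variants = tibble(variant_id = colnames(dos), chrom = 1L,
                        pos = 1000000L + (seq_len(m) - 1L) * 4000L,
                        effect_allele = "A", other_allele = "G", maf = maf,
                        region = "r1", protein_id = NA_character_),
      sample_ids = sprintf("S%06d", seq_len(n))
    ), class = "genotype_matrix")
    compute_summary_stats(g, y, trait_type = "quant")
  }

  list(region1 = make_one(n1, c1), region2 = make_one(n2, c2),
       causal = c(c1, c2))
}

#' Simulate a pathway collection with one enriched set
#'
#' Builds a named list of pathways over the supplied universe: the first
#' pathway contains the `enriched` ids plus random padding, the rest are
#' random draws, so over-representation analysis of a hit set overlapping
#' `enriched` has a known positive.
#'
#' @param universe character vector of protein/gene ids.
#' @param enriched ids to plant in the first pathway.
#' @param n_pathways total number of pathways.
#' @param size_range pathway size range for the random pathways.
#' @param seed optional integer seed.
#' @return named list of character vectors (a pathway collection).
#' @export
simulate_pathways <- function(universe, enriched, n_pathways = 20,
                              size_range = c(5, 15), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  check_that(all(enriched %in% universe), "`enriched` must lie in `universe`")
  out <- vector("list", n_pathways)
  names(out) <- sprintf("pathway_%02d", seq_len(n_pathways))
  pad <- sample(setdiff(universe, enriched),
                min(3, length(setdiff(universe, enriched))))
  out[[1]] <- unique(c(enriched, pad))
  hi <- min(size_range[2], length(universe))
  lo <- min(size_range[1], hi)
  for (k in seq_len(n_pathways)[-1]) {
    out[[k]] <- sample(universe, sample(seq(lo, hi), 1))
  }
  out
}
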