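#' Harmonize exposure and outcome summary statistics into instruments
#'
#' Joins the two tables on `variant_id` and puts both effect estimates on
#' the same effect allele: when the outcome's allele labels are swapped
#' relative to the exposure, its beta is negated and its frequency
#' complemented. Palindromic variants (A/T or C/G) are aligned by allele
#' frequency and dropped as ambiguous when `min(eaf, 1 - eaf) > 0.42` on
#' either side; variants whose allele pairs cannot be reconciled are
#' dropped. The instrument F-statistic `(beta_exposure / se_exposure)^2`
#' is computed here.
#'
#' @param exposure,outcome `summary_stats` tibbles.
#' @param annotation optional tibble `variant_id`, `n_proteins_hit`,
#'   `is_cis` joined onto the instruments for [instrument_qc()].
#' @param palindrome_eaf ambiguity threshold for palindromic variants.
#' @return an instrument tibble (`variant_id`, alleles, `eaf_exposure`,
#'   `eaf_outcome`, `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`, `f_stat`, plus annotation columns). Attribute
#'   `n_dropped` records palindrome/mismatch removals.
#' @export
harmonize <- function(exposure, outcome, annotation = NULL,
                      palindrome_eaf = 0.42) {
  ex <- exposure %>%
    filter(!is.na(.data$se)) %>%
    select("variant_id", "effect_allele", "other_allele",
           eaf_exposure = "eaf", beta_exposure = "beta", se_exposure = "se")
  ou <- outcome %>%
    filter(!is.na(.data$se)) %>%
    select("variant_id", o_effect = "effect_allele", o_other = "other_allele",
           eaf_outcome = "eaf", beta_outcome = "beta", se_outcome = "se")
  m <- inner_join(ex, ou, by = "variant_id")
  check_that(nrow(m) > 0, "no shared variants between exposure and outcome")

  same <- m$effect_allele == m$o_effect & m$other_allele == m$o_other
  swapped <- m$effect_allele == m$o_other & m$other_allele == m$o_effect
  pal <- is_palindromic(m$effect_allele, m$other_allele)

  m$beta_outcome[swapped] <- -m$beta_outcome[swapped]
  m$eaf_outcome[swapped] <- 1 - m$eaf_outcome[swapped]

  keep <- same | swapped
  # palindromes: allele labels cannot distinguish strands; align by
  # frequency, drop when the frequency itself is uninformative
  ambiguous <- pal & (pmin(m$eaf_exposure, 1 - m$eaf_exposure) > palindrome_eaf |
                        pmin(m$eaf_outcome, 1 - m$eaf_outcome) > palindrome_eaf)
  flip_by_freq <- pal & !ambiguous & keep &
    ((m$eaf_exposure - 0.5) * (m$eaf_outcome - 0.5) < 0)
  m$beta_outcome[flip_by_freq] <- -m$beta_outcome[flip_by_freq]
  m$eaf_outcome[flip_by_freq] <- 1 - m$eaf_outcome[flip_by_freq]
  keep <- keep & !ambiguous

  out <- m %>%
    filter(keep) %>%
    select(-"o_effect", -"o_other") %>%
    mutate(f_stat = (.data$beta_exposure / .data$se_exposure)^2)
  if (!is.null(annotation)) {
    out <- left_join(out, annotation, by = "variant_id")
  }
  attr(out, "n_dropped") <- nrow(m) - nrow(out)
  out
}

is_palindromic <- function(a1, a2) {
  p <- paste0(a1, a2)
  p %in% c("AT", "TA", "CG", "GC")
}

#' Instrument quality control
#'
#' Drops weak instruments (`f_stat < f_min`) and pleiotropic pQTLs
#' (variants that are pQTLs for more than `pleiotropy_max` proteins, i.e.
#' the "5 or more" rule at the default). In cis-only mode the analysis is
#' skipped (reported, not raised) when fewer than `min_cis` cis
#' instruments survive.
#'
#' @param instruments tibble from [harmonize()]; `n_proteins_hit` and
#'   `is_cis` columns are honoured when present.
#' @param f_min minimum instrument F-statistic.
#' @param pleiotropy_max maximum number of proteins a pQTL may hit
#'   (dropped when hitting `pleiotropy_max + 1` or more).
#' @param min_cis minimum surviving cis instruments in cis-only mode.
#' @param cis_only restrict to cis instruments and apply the `min_cis`
#'   gate.
#' @return the filtered tibble; attributes `skip` (logical) and
#'   `skip_reason`.
#' @export
instrument_qc <- function(instruments, f_min = 10, pleiotropy_max = 4,
                          min_cis = 3, cis_only = FALSE) {
  out <- instruments %>% filter(.data$f_stat >= f_min)
  if ("n_proteins_hit" %in% names(out)) {
    out <- out %>% filter(is.na(.data$n_proteins_hit) |
                            .data$n_proteins_hit <= pleiotropy_max)
  }
  skip <- FALSE
  reason <- NA_character_
  if (cis_only) {
    if ("is_cis" %in% names(out)) out <- out %>% filter(.data$is_cis)
    if (nrow(out) < min_cis) {
      skip <- TRUE
      reason <- sprintf("only %d cis instrument(s) after QC (< %d)",
                        nrow(out), min_cis)
    }
  }
  attr(out, "skip") <- skip
  attr(out, "skip_reason") <- reason
  out
}

mr_fit_row <- function(method, estimate, se, pval, n_instruments,
                       cochran_q = NA_real_, q_pval = NA_real_) {
  tibble(method = method, estimate = estimate, se = se, pval = pval,
         n_instruments = n_instruments, cochran_q = cochran_q,
         q_pval = q_pval)
}

#' Inverse-variance-weighted MR estimator
#'
#' Fixed-effect IVW: weighted least squares of the outcome betas on the
#' exposure betas through the origin with weights `1 / se_outcome^2`,
#' `estimate = sum(bx by / sy^2) / sum(bx^2 / sy^2)` and
#' `se = sqrt(1 / sum(bx^2 / sy^2))`. With a single instrument this
#' reduces to the Wald ratio `by / bx` with `se = sy / |bx|`. Cochran's Q
#' (df J - 1) is reported for heterogeneity.
#'
#' @param instruments harmonized instrument tibble.
#' @return one-row fit tibble (`method = "ivw"`, or `"wald"` at J = 1).
#' @export
ivw <- function(instruments) {
  j <- nrow(instruments)
  check_that(j >= 1, "no instruments")
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  sy <- instruments$se_outcome
  wsum <- sum(bx^2 / sy^2)
  est <- sum(bx * by / sy^2) / wsum
  se <- sqrt(1 / wsum)
  q <- sum((by - est * bx)^2 / sy^2)
  mr_fit_row(if (j == 1) "wald" else "ivw", est, se, p_normal(est, se), j,
             cochran_q = if (j > 1) q else NA_real_,
             q_pval = if (j > 1) pchisq(q, df = j - 1, lower.tail = FALSE)
                      else NA_real_)
}

#' Simple and weighted median MR estimators
#'
#' Per-instrument Wald ratios `r_j = by_j / bx_j` are ordered; with
#' normalized weights `w_j` (equal for the simple median,
#' `bx_j^2 / sy_j^2` for the weighted median) and cumulative sums `S_j`,
#' the estimate is the ratio at cumulative probability
#' `p_j = (S_j - w_j / 2) / sum(w)` linearly interpolated to `p = 0.5`.
#' The standard error is a parametric bootstrap: instrument betas are
#' redrawn from normal errors around their estimates and the median
#' recomputed.
#'
#' @param instruments harmonized instrument tibble (>= 3 rows).
#' @param weighted use inverse-variance ratio weights.
#' @param n_boot parametric bootstrap draws for the SE.
#' @param seed integer seed.
#' @return one-row fit tibble.
#' @export
median_mr <- function(instruments, weighted = TRUE, n_boot = 1000, seed = 1) {
  j <- nrow(instruments)
  check_that(j >= 3, "median MR needs >= 3 instruments (got %d)", j)
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  sx <- instruments$se_exposure
  sy <- instruments$se_outcome
  wts <- if (weighted) bx^2 / sy^2 else rep(1, j)
  est <- weighted_median_interp(by / bx, wts)

  set.seed(as.integer(seed))
  boot <- vapply(seq_len(n_boot), function(k) {
    bxs <- bx + rnorm(j, 0, sx)
    bys <- by + rnorm(j, 0, sy)
    w <- if (weighted) bxs^2 / sy^2 else rep(1, j)
    weighted_median_interp(bys / bxs, w)
  }, numeric(1))
  se <- sd(boot)
  if (!is.finite(se) || se == 0) se <- .Machine$double.eps
  mr_fit_row(if (weighted) "weighted_median" else "simple_median",
             est, se, p_normal(est, se), j)
}

# interpolated cumulative-weight median of x
weighted_median_interp <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (p[1] >= 0.5) return(x[1])
  if (p[length(p)] <= 0.5) return(x[length(x)])
  stats::approx(p, x, xout = 0.5, ties = "ordered")$y
}

#' MR-Egger regression
#'
#' Instruments are oriented so every exposure beta is non-negative (both
#' betas of a pair are negated together), then outcome betas are
#' regressed on exposure betas by weighted least squares with an
#' intercept, weights `1 / se_outcome^2`. The slope is the causal
#' estimate; the intercept is the directional-pleiotropy test. Both use t
#' tests with J - 2 degrees of freedom.
#'
#' @param instruments harmonized instrument tibble (>= 3 rows).
#' @return two-row fit tibble (`egger_slope`, `egger_intercept`).
#' @export
egger <- function(instruments) {
  j <- nrow(instruments)
  check_that(j >= 3, "MR-Egger needs >= 3 instruments (got %d)", j)
  flip <- sign(instruments$beta_exposure)
  flip[flip == 0] <- 1
  bx <- instruments$beta_exposure * flip
  by <- instruments$beta_outcome * flip
  w <- 1 / instruments$se_outcome^2
  fit <- lm(by ~ bx, weights = w)
  co <- summary(fit)$coefficients
  bind_rows(
    mr_fit_row("egger_slope", co["bx", 1], co["bx", 2], co["bx", 4], j),
    mr_fit_row("egger_intercept", co["(Intercept)", 1], co["(Intercept)", 2],
               co["(Intercept)", 4], j)
  )
}

#' Run the four conventional MR estimators
#'
#' IVW, simple median, weighted median, and MR-Egger on one harmonized
#' instrument set. With one or two instruments only the estimators whose
#' requirements are met are returned (Wald/IVW).
#'
#' @inheritParams median_mr
#' @return fit tibble with one row per method (Egger contributes a slope
#'   and an intercept row).
#' @export
mr_all <- function(instruments, n_boot = 1000, seed = 1) {
  j <- nrow(instruments)
  check_that(j >= 1, "no instruments")
  fits <- list(ivw(instruments))
  if (j >= 3) {
    fits <- c(fits, list(
      median_mr(instruments, weighted = FALSE, n_boot = n_boot, seed = seed),
      median_mr(instruments, weighted = TRUE, n_boot = n_boot,
                seed = seed + 1L),
      egger(instruments)
    ))
  }
  bind_rows(fits)
}

#' Median-p consensus across MR methods
#'
#' For each exposure (protein), the consensus p-value is the median of
#' the four conventional method p-values (IVW, simple median, weighted
#' median, Egger slope) -- the mean of the 2nd and 3rd order statistics.
#' Proteins with an Egger intercept p below `pleiotropy_alpha` are
#' flagged as pleiotropic and excluded from the significant set
#' regardless of their consensus p. BH FDR is applied across proteins,
#' and Bonferroni significance uses `alpha / (n_proteins * 4)` families
#' unless `bonferroni_threshold` overrides it.
#'
#' @param fits tibble of per-method fits with a `protein_id` column
#'   (stack of [mr_all()] outputs).
#' @param alpha significance level.
#' @param pleiotropy_alpha Egger-intercept flag level.
#' @param bonferroni_threshold optional explicit Bonferroni threshold.
#' @return an `mr_consensus` tibble: `protein_id`, `median_p`,
#'   `pleiotropy_flag`, `fdr_q`, `bonferroni_sig`, `significant`, and the
#'   IVW estimate carried along for reporting.
#' @export
consensus <- function(fits, alpha = 0.05, pleiotropy_alpha = 0.05,
                      bonferroni_threshold = NULL) {
  check_that("protein_id" %in% names(fits), "fits need a protein_id column")
  four <- c("ivw", "wald", "simple_median", "weighted_median", "egger_slope")
  per <- fits %>%
    group_by(.data$protein_id) %>%
    summarise(
      median_p = median_p4(.data$pval[.data$method %in% four]),
      pleiotropy_flag = any(.data$method == "egger_intercept" &
                              .data$pval < pleiotropy_alpha),
      ivw_estimate = .data$estimate[.data$method %in% c("ivw", "wald")][1],
      ivw_se = .data$se[.data$method %in% c("ivw", "wald")][1],
      n_instruments = max(.data$n_instruments),
      .groups = "drop"
    )
  m <- nrow(per)
  bonf <- bonferroni_threshold %||% bonferroni_threshold(alpha, m, 4)
  out <- per %>%
    mutate(fdr_q = bh_fdr(.data$median_p),
           bonferroni_sig = .data$median_p < bonf & !.data$pleiotropy_flag,
           significant = .data$fdr_q < alpha & !.data$pleiotropy_flag) %>%
    structure(class = c("mr_consensus", class(tibble())))
  attr(out, "bonferroni_threshold") <- bonf
  out
}

# median of the method p-values; for the canonical 4 methods this is the
# mean of the 2nd and 3rd order statistics
median_p4 <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) return(NA_real_)
  median(p)
}

#' Reverse Mendelian randomisation: trait as exposure, proteins as outcome
#'
#' Instruments are genome-wide-significant trait variants selected by
#' [clump()] (default 500 kb window, p < 5e-8, r-squared < 0.001), then
#' each protein's summary statistics are harmonized as the outcome and
#' the full four-method pipeline plus consensus is run. Returns an empty
#' consensus (with a skip reason) when the trait has no significant
#' variants.
#'
#' @param trait_sumstats trait GWAS `summary_stats`.
#' @param protein_sumstats named list of protein `summary_stats`.
#' @param ld_source `genotype_matrix` for clumping LD.
#' @param params reverse-MR [clump_params()].
#' @param n_boot,seed passed to the median bootstrap.
#' @return list with `consensus` (an `mr_consensus` tibble), `fits`, and
#'   `skip_reason` (`NA` when run).
#' @export
reverse_mr <- function(trait_sumstats, protein_sumstats, ld_source,
                       params = clump_params(5e-8, 0.001, 500),
                       n_boot = 1000, seed = 1) {
  idx <- clump(trait_sumstats, ld_source, params)
  if (nrow(idx) == 0) {
    return(list(consensus = NULL, fits = NULL,
                skip_reason = "no genome-wide-significant trait variants"))
  }
  trait_iv <- trait_sumstats %>% filter(.data$variant_id %in% idx$variant_id)
  fits <- purrr::imap_dfr(protein_sumstats, function(ss, pid) {
    instr <- tryCatch(harmonize(trait_iv, ss), error = function(e) NULL)
    if (is.null(instr) || nrow(instr) == 0) return(NULL)
    instr <- instrument_qc(instr)
    if (nrow(instr) == 0) return(NULL)
    mr_all(instr, n_boot = n_boot, seed = seed) %>%
      mutate(protein_id = pid, .before = 1)
  })
  if (nrow(fits) == 0) {
    return(list(consensus = NULL, fits = NULL,
                skip_reason = "no proteins with usable instruments"))
  }
  list(consensus = consensus(fits), fits = fits, skip_reason = NA_character_)
}

#' Fixed-effect inverse-variance meta-analysis of summary statistics
#'
#' Combines per-stratum GWAS tables variant by variant (trans-ancestry
#' sensitivity analyses); effect alleles must already agree.
#'
#' @param stats_list list of `summary_stats` tibbles.
#' @return a `summary_stats` tibble with meta-analysed `beta`, `se`,
#'   `pval`, pooled `n`, and sample-size-weighted `eaf`.
#' @export
meta_sumstats <- function(stats_list) {
  check_that(length(stats_list) >= 2, "need at least two tables to meta-analyse")
  long <- bind_rows(stats_list, .id = ".stratum") %>% filter(!is.na(.data$se))
  long %>%
    group_by(.data$variant_id) %>%
    summarise(
      chrom = .data$chrom[1], pos = .data$pos[1],
      effect_allele = .data$effect_allele[1],
      other_allele = .data$other_allele[1],
      eaf = sum(.data$eaf * .data$n) / sum(.data$n),
      beta = sum(.data$beta / .data$se^2) / sum(1 / .data$se^2),
      se = sqrt(1 / sum(1 / .data$se^2)),
      n = sum(.data$n),
      trait_type = .data$trait_type[1],
      case_prop = .data$case_prop[1],
      .groups = "drop"
    ) %>%
    mutate(pval = p_normal(.data$beta, .data$se)) %>%
    select("variant_id", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "beta", "se", "pval", "n", "trait_type", "case_prop") %>%
    structure(class = c("summary_stats", class(tibble())))
}
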