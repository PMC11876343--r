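#' Default cohort covariates for the synthetic analyses
#'
#' Age, sex, their interaction, and genetic PCs 1-10, built from a cohort
#' tibble. Additional columns can be appended by name.
#'
#' @param cohort a cohort tibble.
#' @param extra optional character vector of extra cohort columns.
#' @return a data frame of numeric covariates.
#' @export
cohort_covariates <- function(cohort, extra = NULL) {
  out <- data.frame(age = cohort$age, sex = cohort$sex,
                    age_sex = cohort$age * cohort$sex)
  for (p in paste0("pc", 1:10)) if (p %in% names(cohort)) out[[p]] <- cohort[[p]]
  for (e in extra) {
    check_that(e %in% names(cohort), "covariate column `%s` not in cohort", e)
    out[[e]] <- cohort[[e]]
  }
  out
}

#' Single linear association with covariate adjustment
#'
#' Least-squares fit of `y` on `[1, x, covariates]`; reports the
#' coefficient of `x` with its t-based two-sided p-value and the partial
#' r-squared `t^2 / (t^2 + df)`. Rank-deficient designs raise a
#' collinearity error naming the aliased columns.
#'
#' @param y outcome vector.
#' @param x predictor of interest.
#' @param covariates optional data frame.
#' @return one-row tibble: `beta`, `se`, `t_stat`, `pval`, `r2_partial`,
#'   `n`.
#' @export
linear_assoc <- function(y, x, covariates = NULL) {
  check_that(length(y) == length(x), "y/x length mismatch")
  X <- cbind(covariate_design(covariates, length(y)), x = x)
  cc <- complete.cases(X) & is.finite(y)
  X <- X[cc, , drop = FALSE]
  yv <- y[cc]
  check_that(nrow(X) > ncol(X) + 1, "too few rows for the design")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("collinear design; aliased column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta_all <- qr.coef(qx, yv)
  res <- yv - drop(X %*% beta_all)
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * XtXinv[ncol(X), ncol(X)])
  b <- beta_all[["x"]]
  t_stat <- b / se
  tibble(beta = b, se = se, t_stat = t_stat,
         pval = 2 * pt(-abs(t_stat), df),
         r2_partial = if (is.finite(t_stat)) t_stat^2 / (t_stat^2 + df) else 1,
         n = nrow(X))
}

#' Remove samples with prevalent disease
#'
#' @param cohort a cohort tibble with a `prevalent_disease` flag.
#' @return the filtered cohort; attribute `n_removed` counts removals.
#' @export
filter_prevalent <- function(cohort) {
  check_that("prevalent_disease" %in% names(cohort),
             "cohort lacks a prevalent_disease column")
  out <- cohort %>% filter(.data$prevalent_disease == 0)
  attr(out, "n_removed") <- nrow(cohort) - nrow(out)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q_i = min_{j >= i} (p_(j) * m / j)`, monotone
#' and capped at 1 (delegates to [stats::p.adjust()]).
#'
#' @param pvals numeric vector of p-values in `(0, 1]`.
#' @return vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  p.adjust(pvals, method = "BH")
}

#' Bonferroni threshold for a two-dimensional test family
#'
#' `alpha / (n_a * n_b)` -- the discovery rule for a scan of `n_a` scores
#' against `n_b` proteins (at the study scale of 10 scores and 2922
#' proteins this is 1.7e-6), and equally the reverse-MR rule for
#' `n_a` proteins by `n_b` MR methods.
#'
#' @param alpha family-wise error rate.
#' @param n_a,n_b the two family dimensions.
#' @return the per-test threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_a = 1, n_b = 1) {
  check_number(alpha, "alpha", lower = 0, upper = 1, open_lower = TRUE)
  check_number(n_a, "n_a", lower = 1, integer = TRUE)
  check_number(n_b, "n_b", lower = 1, integer = TRUE)
  alpha / (n_a * n_b)
}

#' Two-stage PGS-protein association scan
#'
#' Stage one regresses every standardized protein on every standardized
#' score in the discovery stratum (covariate-adjusted) and applies a
#' Bonferroni threshold `alpha / (n_scores * n_proteins)`. Stage two
#' re-tests only the discovery-significant pairs in the replication
#' stratum and applies Benjamini-Hochberg FDR *within each score*; a pair
#' is replicated iff its within-score q-value is below `fdr_q`.
#'
#' @param cohort a cohort tibble (filter prevalent disease first; an empty
#'   cohort raises an error).
#' @param scores a tibble with `sample_id` plus one standardized-score
#'   column per score.
#' @param protein_ids protein columns to scan; defaults to every
#'   `protein_*` column.
#' @param alpha family-wise error rate for the discovery Bonferroni.
#' @param fdr_q replication FDR level.
#' @param extra_covariates optional extra cohort columns (e.g. `"bmi"`) or
#'   a data frame of per-sample columns (e.g. pQTL dosages) appended to the
#'   adjustment set.
#' @return a `scan_report`: list with `discovery`, `replication` tibbles,
#'   `threshold`, `alpha`, `fdr_q`, and counts.
#' @export
run_scan <- function(cohort, scores, protein_ids = NULL, alpha = 0.05,
                     fdr_q = 0.05, extra_covariates = NULL) {
  check_that(nrow(cohort) > 0, "empty cohort")
  protein_ids <- protein_ids %||% grep("^protein_", names(cohort), value = TRUE)
  score_ids <- setdiff(names(scores), "sample_id")
  check_that(length(score_ids) > 0 && length(protein_ids) > 0,
             "need at least one score and one protein")
  threshold <- bonferroni_threshold(alpha, length(score_ids),
                                    length(protein_ids))

  dat <- cohort %>% inner_join(scores, by = "sample_id")
  check_that(nrow(dat) > 0, "no overlap between cohort and score samples")

  stage <- function(stratum_name) {
    d <- dat %>% filter(.data$stratum == stratum_name)
    if (nrow(d) == 0) return(NULL)
    covs <- cohort_covariates(d)
    if (is.data.frame(extra_covariates)) {
      ex <- extra_covariates[match(d$sample_id, extra_covariates$sample_id), ,
                             drop = FALSE]
      covs <- cbind(covs, ex[, setdiff(names(ex), "sample_id"), drop = FALSE])
    } else if (!is.null(extra_covariates)) {
      covs <- cohort_covariates(d, extra = extra_covariates)
    }
    purrr::map_dfr(score_ids, function(sid) {
      s <- standardize(d[[sid]], sid)
      purrr::map_dfr(protein_ids, function(pid) {
        linear_assoc(standardize(d[[pid]], pid), s, covs) %>%
          mutate(score_id = sid, protein_id = pid, .before = 1)
      })
    })
  }

  discovery <- stage("discovery") %>%
    mutate(significant = .data$pval < threshold)
  hits <- discovery %>% filter(.data$significant)

  replication <- NULL
  if (nrow(hits) > 0) {
    rep_all <- stage("replication")
    if (!is.null(rep_all)) {
      replication <- hits %>%
        select("score_id", "protein_id") %>%
        inner_join(rep_all, by = c("score_id", "protein_id")) %>%
        group_by(.data$score_id) %>%
        mutate(qval = bh_fdr(.data$pval)) %>%
        ungroup() %>%
        mutate(replicated = .data$qval < fdr_q)
    }
  }
  if (is.null(replication)) {
    replication <- tibble(score_id = character(), protein_id = character(),
                          beta = numeric(), se = numeric(), t_stat = numeric(),
                          pval = numeric(), r2_partial = numeric(),
                          n = integer(), qval = numeric(), replicated = logical())
  }

  structure(list(
    discovery = discovery,
    replication = replication,
    threshold = threshold,
    alpha = alpha,
    fdr_q = fdr_q,
    n_scores = length(score_ids),
    n_proteins = length(protein_ids)
  ), class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf("<scan_report> %d scores x %d proteins; Bonferroni %.3g\n",
              x$n_scores, x$n_proteins, x$threshold))
  cat(sprintf("  discovery significant: %d; replicated: %d\n",
              sum(x$discovery$significant), sum(x$replication$replicated)))
  invisible(x)
}

#' Association scan with extra adjustment and attenuation classification
#'
#' Re-runs [run_scan()] with extra covariates (BMI, waist circumference,
#' waist-hip ratio, or per-sample pQTL dosages) and classifies every
#' baseline discovery-significant pair as `still_significant` or
#' `attenuated_to_nonsignificance`. Pairs significant *only after*
#' adjustment are flagged `gained_after_adjustment` and excluded from
#' headline counts, since conditioning on a downstream variable can induce
#' collider bias.
#'
#' @param cohort,scores,protein_ids,alpha,fdr_q as in [run_scan()].
#' @param extra `"bmi"`, `"wc"`, `"whr"`, or a data frame of `sample_id`
#'   plus pQTL dosage columns.
#' @param baseline optional precomputed unadjusted `scan_report`.
#' @return list with the adjusted `report`, the `classification` tibble
#'   (`score_id`, `protein_id`, `status`), and `gained` (flagged pairs).
#' @export
adjusted_scan <- function(cohort, scores, extra, protein_ids = NULL,
                          alpha = 0.05, fdr_q = 0.05, baseline = NULL) {
  if (is.character(extra)) {
    check_that(all(extra %in% c("bmi", "wc", "whr")),
               "character `extra` must be bmi, wc, and/or whr")
  }
  baseline <- baseline %||% run_scan(cohort, scores, protein_ids, alpha, fdr_q)
  adjusted <- run_scan(cohort, scores, protein_ids, alpha, fdr_q,
                       extra_covariates = extra)

  base_sig <- baseline$discovery %>% select("score_id", "protein_id", "significant")
  adj_sig <- adjusted$discovery %>%
    select("score_id", "protein_id", adj_significant = "significant")
  both <- inner_join(base_sig, adj_sig, by = c("score_id", "protein_id"))

  classification <- both %>%
    filter(.data$significant) %>%
    mutate(status = ifelse(.data$adj_significant, "still_significant",
                           "attenuated_to_nonsignificance")) %>%
    select("score_id", "protein_id", "status")
  gained <- both %>%
    filter(!.data$significant, .data$adj_significant) %>%
    mutate(status = "gained_after_adjustment") %>%
    select("score_id", "protein_id", "status")

  list(report = adjusted, classification = classification, gained = gained)
}

#' Compare two sets of association betas
#'
#' Pearson correlation and OLS slope of `results_b`'s betas on
#' `results_a`'s over proteins present in both, optionally restricted to
#' pairs significant in `results_a`.
#'
#' @param results_a,results_b association tibbles with `protein_id`,
#'   `beta`, `pval` columns.
#' @param subset `"all"` or `"significant_only"`.
#' @param sig_threshold significance cut applied to `results_a$pval` for
#'   the `significant_only` subset.
#' @return one-row tibble: `pearson_r`, `slope`, `pval`, `n`.
#' @export
compare_betas <- function(results_a, results_b,
                          subset = c("all", "significant_only"),
                          sig_threshold = 0.05) {
  subset <- match.arg(subset)
  merged <- inner_join(
    results_a %>% select("protein_id", beta_a = "beta", pval_a = "pval"),
    results_b %>% select("protein_id", beta_b = "beta"),
    by = "protein_id"
  )
  if (subset == "significant_only") {
    merged <- merged %>% filter(.data$pval_a < sig_threshold)
  }
  check_that(nrow(merged) >= 3, "fewer than 3 matched pairs")
  ct <- cor.test(merged$beta_a, merged$beta_b)
  slope <- coef(lm(beta_b ~ beta_a, data = merged))[["beta_a"]]
  tibble(pearson_r = unname(ct$estimate), slope = slope,
         pval = ct$p.value, n = nrow(merged))
}
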