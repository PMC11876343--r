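#' Natural-effects mediation for a continuous mediator and outcome
#'
#' Product-of-coefficients decomposition for the linear chain
#' exposure -> mediator -> outcome: fits `mediator ~ exposure + C`
#' (coefficient `a`) and `outcome ~ exposure + mediator + C`
#' (coefficients `c'` and `b`), giving natural indirect effect
#' `nie = a * b`, natural direct effect `nde = c'`, and total effect
#' `te = nde + nie` (exact on the linear scale). Point estimates are
#' deterministic; confidence intervals and p-values come from a
#' row-resampling percentile bootstrap.
#'
#' @param data data frame holding all columns.
#' @param exposure,mediator,outcome column names.
#' @param covariates character vector of covariate column names, or a data
#'   frame with the same rows.
#' @param n_boot bootstrap replicates (>= 100; the refusal guards against
#'   meaningless percentile intervals).
#' @param seed integer seed for the bootstrap.
#' @param conf_level confidence level for the percentile intervals.
#' @return a one-row `mediation_result` tibble: `nde`, `nie`, `te`,
#'   `prop_mediated` (`NA` and flagged when `nde` and `nie` disagree in
#'   sign), `p_direct`, `p_indirect`, `p_total`, per-effect `ci_low_*` /
#'   `ci_high_*`, `n`, `n_boot`, `scale`, `discordant`. The fitted
#'   quantities needed by [sensitivity_rho()] are stored as attributes.
#' @export
mediate_continuous <- function(data, exposure, mediator, outcome,
                               covariates = NULL, n_boot = 1000, seed = 1,
                               conf_level = 0.95) {
  check_that(n_boot >= 100, "n_boot = %d is too few replicates (>= 100)", n_boot)
  mats <- mediation_design(data, exposure, mediator, outcome, covariates)
  n <- nrow(mats$C)
  check_that(n > ncol(mats$C) + 3, "too few rows for the mediation design")

  point <- linear_paths(mats$x, mats$m, mats$y, mats$C)

  set.seed(as.integer(seed))
  draws <- matrix(NA_real_, nrow = n_boot, ncol = 3,
                  dimnames = list(NULL, c("nde", "nie", "te")))
  for (bidx in seq_len(n_boot)) {
    i <- sample.int(n, n, replace = TRUE)
    pb <- linear_paths(mats$x[i], mats$m[i], mats$y[i], mats$C[i, , drop = FALSE])
    draws[bidx, ] <- c(pb$nde, pb$nie, pb$nde + pb$nie)
  }

  res <- mediation_summary(point$nde, point$nie, draws, n = n,
                           n_boot = n_boot, scale = "linear",
                           conf_level = conf_level)
  attr(res, "paths") <- point
  res
}

# assemble x/m/y/C matrices with complete cases
mediation_design <- function(data, exposure, mediator, outcome, covariates) {
  for (col in c(exposure, mediator, outcome)) {
    check_that(col %in% names(data), "column `%s` not found", col)
  }
  C <- if (is.data.frame(covariates)) {
    as.matrix(covariates)
  } else if (is.character(covariates)) {
    as.matrix(data[, covariates, drop = FALSE])
  } else {
    matrix(numeric(0), nrow = nrow(data), ncol = 0)
  }
  keep <- complete.cases(data[, c(exposure, mediator, outcome)]) &
    (if (ncol(C) > 0) complete.cases(C) else TRUE)
  list(x = data[[exposure]][keep], m = data[[mediator]][keep],
       y = data[[outcome]][keep], C = C[keep, , drop = FALSE])
}

# a / b / c' coefficients and residual SDs via least squares
linear_paths <- function(x, m, y, C) {
  X1 <- cbind(1, x, C)
  f1 <- .lm.fit(X1, m)
  a <- f1$coefficients[2]
  X2 <- cbind(1, x, m, C)
  f2 <- .lm.fit(X2, y)
  cprime <- f2$coefficients[2]
  b <- f2$coefficients[3]
  list(a = a, b = b, cprime = cprime,
       nde = cprime, nie = a * b,
       sd_m_resid = sqrt(sum(f1$residuals^2) / (length(m) - ncol(X1))),
       sd_y_resid = sqrt(sum(f2$residuals^2) / (length(y) - ncol(X2))))
}

mediation_summary <- function(nde, nie, draws, n, n_boot, scale, conf_level) {
  te <- nde + nie
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  ci <- apply(draws, 2, quantile, probs = probs, na.rm = TRUE)
  discordant <- nde * nie < 0
  tibble(
    nde = nde, nie = nie, te = te,
    prop_mediated = if (discordant) NA_real_ else nie / te,
    p_direct = boot_p(draws[, "nde"]),
    p_indirect = boot_p(draws[, "nie"]),
    p_total = boot_p(draws[, "te"]),
    ci_low_nde = ci[1, "nde"], ci_high_nde = ci[2, "nde"],
    ci_low_nie = ci[1, "nie"], ci_high_nie = ci[2, "nie"],
    ci_low_te = ci[1, "te"], ci_high_te = ci[2, "te"],
    n = n, n_boot = n_boot, scale = scale, discordant = discordant
  ) %>% structure(class = c("mediation_result", class(tibble())))
}

#' Natural-effects mediation for a binary outcome (imputation approach)
#'
#' Imputation-based natural-effects estimation on the log-odds scale:
#' a logistic imputation model `outcome ~ exposure + mediator + C` is fit
#' on the observed data; each row is then duplicated with a counterfactual
#' direct-path exposure `x*` drawn (by permutation) from the observed
#' exposure distribution while the mediator path keeps the observed
#' exposure, the expected outcome is imputed from the model, and the
#' natural-effects logistic model `y_imputed ~ x_direct + x_mediator + C`
#' is fit on the expanded data. The `x_direct` coefficient is the natural
#' direct effect and the `x_mediator` coefficient the natural indirect
#' effect, both as log odds ratios per unit exposure. The whole procedure
#' (including the expansion) is bootstrapped.
#'
#' @inheritParams mediate_continuous
#' @param min_events minimum number of outcome events required.
#' @return a one-row `mediation_result` tibble on the `log_odds` scale;
#'   `prop_mediated = nie / (nde + nie)`.
#' @export
mediate_binary <- function(data, exposure, mediator, outcome,
                           covariates = NULL, n_boot = 500, seed = 1,
                           conf_level = 0.95, min_events = 20) {
  check_that(n_boot >= 100, "n_boot = %d is too few replicates (>= 100)", n_boot)
  mats <- mediation_design(data, exposure, mediator, outcome, covariates)
  check_that(all(mats$y %in% c(0, 1)), "outcome must be binary 0/1")
  check_that(sum(mats$y) >= min_events,
             "insufficient events: %d < %d", sum(mats$y), min_events)

  set.seed(as.integer(seed))
  point <- natural_effects_binary(mats$x, mats$m, mats$y, mats$C)

  n <- length(mats$y)
  draws <- matrix(NA_real_, nrow = n_boot, ncol = 3,
                  dimnames = list(NULL, c("nde", "nie", "te")))
  for (bidx in seq_len(n_boot)) {
    i <- sample.int(n, n, replace = TRUE)
    pb <- tryCatch(
      natural_effects_binary(mats$x[i], mats$m[i], mats$y[i],
                             mats$C[i, , drop = FALSE]),
      error = function(e) NULL
    )
    if (!is.null(pb)) draws[bidx, ] <- c(pb$nde, pb$nie, pb$nde + pb$nie)
  }

  mediation_summary(point$nde, point$nie, draws, n = n, n_boot = n_boot,
                    scale = "log_odds", conf_level = conf_level)
}

# one pass of the imputation-based natural-effects fit
natural_effects_binary <- function(x, m, y, C) {
  n <- length(y)
  Ximp <- cbind(1, x = x, m = m, C)
  imp <- suppressWarnings(glm.fit(Ximp, y, family = binomial(),
                                  control = list(epsilon = 1e-9, maxit = 50)))
  cf <- imp$coefficients
  xstar <- x[sample.int(n, n)]  # counterfactual direct-path exposure

  # expanded data: (x0 = x, x1 = x) keeps the observed world;
  # (x0 = x*, x1 = x) moves only the direct path
  lin <- function(x0) drop(cbind(1, x0, m, C) %*% cf)
  y_obs <- plogis(lin(x))
  y_cf <- plogis(lin(xstar))
  x0 <- c(x, xstar)
  x1 <- c(x, x)
  yimp <- c(y_obs, y_cf)
  Cexp <- rbind(C, C)
  Xne <- cbind(1, x_direct = x0, x_mediator = x1, Cexp)
  ne <- suppressWarnings(glm.fit(Xne, yimp, family = binomial(),
                                 control = list(epsilon = 1e-9, maxit = 50)))
  list(nde = ne$coefficients[2], nie = ne$coefficients[3])
}

#' Classify a mediation result
#'
#' `full` mediation: indirect and total p below `threshold`, direct not;
#' `partial`: all three below with concordant signs; `discordant`: direct
#' and indirect significant with opposite signs; otherwise `none`.
#'
#' @param result a `mediation_result` row.
#' @param threshold significance threshold (the family-size Bonferroni is
#'   supplied by the caller; no family is hard-coded).
#' @return one of `"full"`, `"partial"`, `"none"`, `"discordant"`.
#' @export
classify_mediation <- function(result, threshold = 0.05) {
  pd <- result$p_direct
  pi_ <- result$p_indirect
  pt_ <- result$p_total
  concordant <- result$nde * result$nie >= 0
  if (pi_ < threshold && pd < threshold && !concordant) return("discordant")
  if (pi_ < threshold && pt_ < threshold && pd >= threshold) return("full")
  if (pi_ < threshold && pt_ < threshold && pd < threshold && concordant)
    return("partial")
  "none"
}

#' Mediator-outcome confounding sensitivity for linear mediation
#'
#' Evaluates the indirect effect under a hypothesized correlation `rho`
#' between the mediator-model and outcome-model errors:
#' `nie(rho) = a * (b - rho * sigma_y / sigma_m)` with the residual SDs of
#' the fitted models, and reports the smallest `|rho|` at which the
#' indirect effect crosses zero (linear interpolation between grid
#' points; `Inf` when no sign change occurs inside the grid).
#'
#' @param result a `mediation_result` from [mediate_continuous()].
#' @param rho_grid correlations in `(-1, 1)` to evaluate.
#' @return a `sensitivity_result` list: `grid` tibble (`rho`,
#'   `nie_at_rho`) and `rho_star`.
#' @export
sensitivity_rho <- function(result, rho_grid = seq(-0.9, 0.9, by = 0.05)) {
  paths <- attr(result, "paths")
  check_that(!is.null(paths),
             "sensitivity analysis needs a linear mediate_continuous() result")
  ratio <- paths$sd_y_resid / paths$sd_m_resid
  nie_at <- paths$a * (paths$b - rho_grid * ratio)
  rho_star <- if (paths$b == 0 || paths$a == 0) {
    0
  } else if (abs(paths$b / ratio) <= max(abs(rho_grid))) {
    paths$b / ratio  # closed-form zero of b - rho * sigma_y / sigma_m
  } else {
    Inf
  }
  structure(list(grid = tibble(rho = rho_grid, nie_at_rho = nie_at),
                 rho_star = rho_star),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> rho* = %s (indirect effect crosses 0)\n",
              format(x$rho_star, digits = 3)))
  invisible(x)
}
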