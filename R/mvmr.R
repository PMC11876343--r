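#' Multivariable Mendelian randomisation with two exposures
#'
#' Weighted least squares of the outcome betas on the two exposures' beta
#' columns without intercept, weights `1 / se_outcome^2`. Reports, per
#' exposure, the estimate/SE/p (normal test); the pleiotropy
#' heterogeneity statistic `Q = sum w_j (by_j - t1 bx1_j - t2 bx2_j)^2`
#' against chi-square with J - 2 df; and a conditional F-statistic per
#' exposure: the weighted residual sum of squares of regressing that
#' exposure's betas on the other exposure's betas (weights
#' `1 / se_exposure^2`), divided by J - 1. An analysis is `retained` iff
#' both conditional F exceed `f_min` and the Q p-value exceeds `q_alpha`.
#'
#' @param instruments tibble with `beta_exposure1`, `se_exposure1`,
#'   `beta_exposure2`, `se_exposure2`, `beta_outcome`, `se_outcome`
#'   (>= 3 rows).
#' @param exposure_names labels for the two exposures.
#' @param f_min conditional instrument-strength gate.
#' @param q_alpha pleiotropy gate on the Q p-value.
#' @return an `mvmr_fit`: list with `estimates` tibble (per exposure:
#'   `estimate`, `se`, `pval`, `conditional_f`), `q_pleiotropy`, `q_df`,
#'   `q_pval`, `retained`, `n_instruments`.
#' @export
mvmr <- function(instruments, exposure_names = c("exposure1", "exposure2"),
                 f_min = 10, q_alpha = 0.05) {
  need <- c("beta_exposure1", "se_exposure1", "beta_exposure2",
            "se_exposure2", "beta_outcome", "se_outcome")
  check_that(all(need %in% names(instruments)),
             "instruments need columns: %s", paste(need, collapse = ", "))
  j <- nrow(instruments)
  check_that(j >= 3, "MVMR needs >= 3 instruments (got %d)", j)

  bx1 <- instruments$beta_exposure1
  bx2 <- instruments$beta_exposure2
  by <- instruments$beta_outcome
  w <- 1 / instruments$se_outcome^2

  # an exposure with no instrument signal reduces to univariable IVW on
  # the other exposure
  dead <- c(all(bx1 == 0), all(bx2 == 0))
  if (any(dead)) {
    check_that(!all(dead), "both exposures have all-zero instrument effects")
    live <- which(!dead)
    uni <- ivw(tibble(beta_exposure = if (live == 1) bx1 else bx2,
                      beta_outcome = by,
                      se_outcome = instruments$se_outcome))
    est <- se_v <- c(NA_real_, NA_real_)
    est[live] <- uni$estimate
    se_v[live] <- uni$se
    resid <- by - est[live] * (if (live == 1) bx1 else bx2)
    q <- sum(w * resid^2)
    return(structure(list(
      estimates = tibble(exposure = exposure_names, estimate = est, se = se_v,
                         pval = p_normal(est, se_v),
                         conditional_f = c(NA_real_, NA_real_)),
      q_pleiotropy = q, q_df = j - 2L,
      q_pval = pchisq(q, df = j - 2L, lower.tail = FALSE),
      retained = FALSE, n_instruments = j
    ), class = "mvmr_fit"))
  }

  X <- cbind(bx1, bx2)
  sw <- sqrt(w)
  Xw <- X * sw
  XtX <- crossprod(Xw)
  if (kappa(XtX) > 1e10) {
    stop("singular two-exposure design: instrument effects are collinear",
         call. = FALSE)
  }
  V <- chol2inv(chol(XtX))
  theta <- drop(V %*% crossprod(Xw, by * sw))
  se <- sqrt(diag(V))

  resid <- by - drop(X %*% theta)
  q <- sum(w * resid^2)
  q_df <- j - 2L
  q_pval <- pchisq(q, df = q_df, lower.tail = FALSE)

  cond_f <- c(
    conditional_f(bx1, bx2, instruments$se_exposure1, j),
    conditional_f(bx2, bx1, instruments$se_exposure2, j)
  )

  structure(list(
    estimates = tibble(
      exposure = exposure_names,
      estimate = theta, se = se, pval = p_normal(theta, se),
      conditional_f = cond_f
    ),
    q_pleiotropy = q, q_df = q_df, q_pval = q_pval,
    retained = all(cond_f > f_min) && q_pval > q_alpha,
    n_instruments = j
  ), class = "mvmr_fit")
}

# Weighted RSS of regressing exposure-k betas on the other exposure's
# betas (weights 1/se_k^2), divided by J - 1: large when the exposure has
# instrument signal not explained by the other exposure.
conditional_f <- function(bk, bother, se_k, j) {
  w <- 1 / se_k^2
  g <- sum(w * bk * bother) / sum(w * bother^2)
  sum(w * (bk - g * bother)^2) / (j - 1)
}

#' @export
print.mvmr_fit <- function(x, ...) {
  cat(sprintf("<mvmr_fit> J = %d; Q = %.2f (df %d, p = %.3g); retained: %s\n",
              x$n_instruments, x$q_pleiotropy, x$q_df, x$q_pval, x$retained))
  print(x$estimates)
  invisible(x)
}

#' Simulate summary-level MVMR instruments
#'
#' Two exposures with independent instrument effects (optionally
#' correlated), outcome betas `t1 bx1 + t2 bx2` plus noise at the stated
#' outcome SE. Used by the MVMR recovery and Q-calibration analyses.
#'
#' @param n_instruments J.
#' @param effect1,effect2 true causal effects of the two exposures.
#' @param se_exposure,se_outcome standard errors.
#' @param seed optional integer seed.
#' @return an instrument tibble for [mvmr()].
#' @export
simulate_mvmr_instruments <- function(n_instruments = 50, effect1 = 0.3,
                                      effect2 = 0.2, se_exposure = 0.02,
                                      se_outcome = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  j <- n_instruments
  b1 <- rnorm(j, 0, 0.3)
  b2 <- rnorm(j, 0, 0.3)
  tibble(
    variant_id = sprintf("iv%03d", seq_len(j)),
    beta_exposure1 = b1 + rnorm(j, 0, se_exposure),
    se_exposure1 = se_exposure,
    beta_exposure2 = b2 + rnorm(j, 0, se_exposure),
    se_exposure2 = se_exposure,
    beta_outcome = effect1 * b1 + effect2 * b2 + rnorm(j, 0, se_outcome),
    se_outcome = se_outcome
  )
}
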