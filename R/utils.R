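# Internal numerical and validation helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Log-sum-exp and log-difference in a numerically stable form
#'
#' `logsumexp()` returns log(sum(exp(x))); `logdiffexp()` returns
#' log(exp(a) - exp(b)) and -Inf when the difference underflows (a <= b).
#' Used by the colocalization accumulators, where Bayes factors can exceed
#' the double-precision exponent range.
#'
#' @param x numeric vector of log-scale values.
#' @return a scalar on the log scale.
#' @keywords internal
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @rdname logsumexp
#' @param a,b log-scale scalars with a >= b expected.
#' @keywords internal
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# stopifnot-style check with a formatted message
check_that <- function(ok, msg, ...) {
  if (!isTRUE(ok)) stop(sprintf(msg, ...), call. = FALSE)
  invisible(TRUE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, open_lower = FALSE, open_upper = FALSE) {
  check_that(is.numeric(x) && length(x) == 1L && is.finite(x),
             "`%s` must be a single finite number", name)
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  check_that(lo_ok && hi_ok, "`%s` = %g is out of range", name, x)
  if (integer) check_that(abs(x - round(x)) < 1e-8, "`%s` must be an integer", name)
  invisible(TRUE)
}

# Standardize a numeric vector to mean 0, SD 1; constant input errors.
standardize <- function(x, name = "x") {
  s <- sd(x)
  check_that(is.finite(s) && s > 0, "cannot standardize constant column `%s`", name)
  (x - mean(x)) / s
}

# Two-sided normal p-value from an estimate and its SE.
p_normal <- function(est, se) 2 * pnorm(-abs(est / se))

# Percentile-bootstrap two-sided p-value for H0: theta = 0, by CI inversion.
boot_p <- function(draws) {
  draws <- draws[is.finite(draws)]
  b <- length(draws)
  if (b == 0L) return(NA_real_)
  lo <- (1 + sum(draws <= 0)) / (b + 1)
  hi <- (1 + sum(draws >= 0)) / (b + 1)
  min(1, 2 * min(lo, hi))
}

# Seed derivation: fold a stage label into a base seed, staying < 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
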