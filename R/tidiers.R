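# broom-style tidiers for the package's result objects.

#' Tidy a scan report
#'
#' One row per score-protein pair across both stages.
#'
#' @param x a `scan_report`.
#' @param ... unused.
#' @return a tibble with a `stage` column (`discovery` / `replication`).
#' @method tidy scan_report
#' @export
tidy.scan_report <- function(x, ...) {
  bind_rows(
    x$discovery %>% mutate(stage = "discovery"),
    x$replication %>% mutate(stage = "replication", significant = NA)
  )
}

#' @rdname tidy.scan_report
#' @method glance scan_report
#' @export
glance.scan_report <- function(x, ...) {
  tibble(
    n_scores = x$n_scores, n_proteins = x$n_proteins,
    bonferroni_threshold = x$threshold,
    n_discovery_significant = sum(x$discovery$significant),
    n_replicated = sum(x$replication$replicated)
  )
}

#' Tidy a mediation result
#'
#' Long format: one row per effect (direct, indirect, total) with its
#' bootstrap interval and p-value.
#'
#' @param x a `mediation_result`.
#' @param ... unused.
#' @return a tibble with `effect`, `estimate`, `ci_low`, `ci_high`,
#'   `pval`.
#' @method tidy mediation_result
#' @export
tidy.mediation_result <- function(x, ...) {
  tibble(
    effect = c("direct", "indirect", "total"),
    estimate = c(x$nde, x$nie, x$te),
    ci_low = c(x$ci_low_nde, x$ci_low_nie, x$ci_low_te),
    ci_high = c(x$ci_high_nde, x$ci_high_nie, x$ci_high_te),
    pval = c(x$p_direct, x$p_indirect, x$p_total)
  )
}

#' @rdname tidy.mediation_result
#' @method glance mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble(prop_mediated = x$prop_mediated, scale = x$scale,
         discordant = x$discordant, n = x$n, n_boot = x$n_boot)
}

#' Tidy a multivariable MR fit
#'
#' @param x an `mvmr_fit`.
#' @param ... unused.
#' @return the per-exposure estimate tibble.
#' @method tidy mvmr_fit
#' @export
tidy.mvmr_fit <- function(x, ...) x$estimates

#' @rdname tidy.mvmr_fit
#' @method glance mvmr_fit
#' @export
glance.mvmr_fit <- function(x, ...) {
  tibble(q_pleiotropy = x$q_pleiotropy, q_df = x$q_df, q_pval = x$q_pval,
         retained = x$retained, n_instruments = x$n_instruments)
}
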