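# ggplot2 presentation helpers. Each returns a ggplot object; nothing is
# drawn or written here.

#' Volcano-style view of a PGS-protein scan
#'
#' Discovery betas against -log10 p with the Bonferroni threshold drawn.
#'
#' @param object a `scan_report`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot scan_report
#' @export
autoplot.scan_report <- function(object, ...) {
  d <- object$discovery
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, y = -log10(.data$pval),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$threshold),
                        linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$score_id)) +
    ggplot2::labs(x = "beta (per SD of PGS)", y = "-log10 p",
                  colour = "discovery\nsignificant") +
    ggplot2::theme_minimal()
}

#' Forest plot of MR estimates per protein and method
#'
#' @param object an `mr_consensus`-bearing fits tibble (per-method rows
#'   with `protein_id`, `method`, `estimate`, `se`).
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_mr_forest <- function(object, ...) {
  d <- object %>%
    filter(.data$method != "egger_intercept") %>%
    mutate(ci_low = .data$estimate - qnorm(0.975) * .data$se,
           ci_high = .data$estimate + qnorm(0.975) * .data$se)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$protein_id,
                                  colour = .data$method)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.6), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "causal estimate (log odds per SD)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of colocalization posteriors
#'
#' @param object a `coloc_posterior` row (or several stacked with a
#'   `protein_id` column).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot coloc_posterior
#' @export
autoplot.coloc_posterior <- function(object, ...) {
  id_col <- if ("protein_id" %in% names(object)) "protein_id" else NULL
  d <- object %>%
    tidyr::pivot_longer(dplyr::starts_with("pp_h"),
                        names_to = "hypothesis", values_to = "pp")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$hypothesis, y = .data$pp)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "posterior probability") +
    ggplot2::theme_minimal()
  if (!is.null(id_col)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data[[id_col]]))
  }
  p
}

#' Hazard-ratio forest for a trial endpoint scan
#'
#' @param object an [endpoint_scan()] tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_trial_hr <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$hazard_ratio, y = .data$protein_id,
                               colour = .data$endpoint)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard ratio (per SD, 95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
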