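#' Wakefield log approximate Bayes factor
#'
#' For a variant with effect estimate `beta`, standard error `se` and
#' effect-size prior SD `prior_sd`: with `V = se^2`, `W = prior_sd^2`,
#' `z = beta / se`,
#' `labf = 0.5 * (log(V / (V + W)) + z^2 * W / (V + W))`.
#'
#' @param beta,se per-variant estimate and standard error (vectorised).
#' @param prior_sd prior SD of the true effect.
#' @return log approximate Bayes factor(s) for association vs. null.
#' @export
wakefield_labf <- function(beta, se, prior_sd) {
  check_that(all(is.finite(beta)) && all(is.finite(se)) && all(se > 0),
             "beta/se must be finite with se > 0")
  check_number(prior_sd, "prior_sd", lower = 0, open_lower = TRUE)
  v <- se^2
  w <- prior_sd^2
  z <- beta / se
  0.5 * (log(v / (v + w)) + z^2 * w / (v + w))
}

# prior SD convention: 0.15 * sdY for quantitative traits, 0.20 for
# case-control log odds
coloc_prior_sd <- function(region) {
  tt <- region$trait_type[1] %||% "quant"
  sdy <- attr(region, "sdY") %||% 1
  if (identical(tt, "cc")) 0.20 else 0.15 * sdy
}

#' Single-causal-variant colocalization by approximate Bayes factors
#'
#' Implements the summary-statistics colocalization model for two traits
#' over one region under the one-causal-variant-per-trait assumption.
#' Per-variant log ABFs are accumulated in log space:
#' `L1 = logsum(labf1)`, `L2 = logsum(labf2)`,
#' `L12 = logsum(labf1 + labf2)`; the unnormalized hypothesis weights are
#' H0: 0, H1: `log p1 + L1`, H2: `log p2 + L2`,
#' H3: `log p1 + log p2 + logdiff(L1 + L2, L12)`, H4: `log p12 + L12`,
#' then normalized to posterior probabilities. H3's log-space difference
#' guards against underflow by returning -Inf (pp_h3 = 0) when the
#' subtraction is degenerate.
#'
#' @param region1,region2 `summary_stats` tibbles for the two traits over
#'   the region; variants are intersected by id (>= 2 shared required).
#' @param p1,p2 prior probability a variant is causal for trait 1 / 2.
#' @param p12 prior probability a variant is causal for both.
#' @param prior_sd1,prior_sd2 effect-size prior SDs; default 0.15 * sdY
#'   for quantitative traits (sdY taken as 1 for standardized traits) and
#'   0.20 for case-control.
#' @return a `coloc_posterior`: one-row tibble `pp_h0` .. `pp_h4`,
#'   `n_variants`, plus prior and accumulator attributes.
#' @export
coloc <- function(region1, region2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                  prior_sd1 = NULL, prior_sd2 = NULL) {
  r1 <- region1 %>% filter(!is.na(.data$se))
  r2 <- region2 %>% filter(!is.na(.data$se))
  shared <- intersect(r1$variant_id, r2$variant_id)
  check_that(length(shared) >= 2,
             "insufficient overlap: %d shared variant(s)", length(shared))
  r1 <- r1[match(shared, r1$variant_id), ]
  r2 <- r2[match(shared, r2$variant_id), ]

  sd1 <- prior_sd1 %||% coloc_prior_sd(region1)
  sd2 <- prior_sd2 %||% coloc_prior_sd(region2)
  labf1 <- wakefield_labf(r1$beta, r1$se, sd1)
  labf2 <- wakefield_labf(r2$beta, r2$se, sd2)

  l1 <- logsumexp(labf1)
  l2 <- logsumexp(labf2)
  l12 <- logsumexp(labf1 + labf2)

  lw <- c(
    h0 = 0,
    h1 = log(p1) + l1,
    h2 = log(p2) + l2,
    h3 = log(p1) + log(p2) + logdiffexp(l1 + l2, l12),
    h4 = log(p12) + l12
  )
  denom <- logsumexp(lw)
  pp <- exp(lw - denom)

  out <- tibble(pp_h0 = pp[["h0"]], pp_h1 = pp[["h1"]], pp_h2 = pp[["h2"]],
                pp_h3 = pp[["h3"]], pp_h4 = pp[["h4"]],
                n_variants = length(shared)) %>%
    structure(class = c("coloc_posterior", class(tibble())))
  attr(out, "priors") <- c(p1 = p1, p2 = p2, p12 = p12)
  attr(out, "log_abf_sums") <- c(L1 = l1, L2 = l2, L12 = l12)
  out
}

#' Colocalization decision rule
#'
#' Strong colocalization evidence iff `pp_h3 + pp_h4 > 0.99` and
#' `pp_h4 / pp_h3 > 5`; a zero `pp_h3` with `pp_h4` clearing the sum
#' threshold counts as an infinite ratio (true).
#'
#' @param post a `coloc_posterior` row.
#' @return logical.
#' @export
coloc_decision <- function(post) {
  ratio <- if (post$pp_h3 == 0) Inf else post$pp_h4 / post$pp_h3
  (post$pp_h3 + post$pp_h4 > 0.99) && (ratio > 5)
}

#' Select candidate colocalization region pairs
#'
#' Every variant with p below `p_threshold` in *both* GWAS seeds a region
#' of `window_kb` kb either side of its position (1-based inclusive,
#' floored at 1); overlapping seed regions on the same chromosome are
#' merged.
#'
#' @param gwas1,gwas2 position-annotated `summary_stats`.
#' @param p_threshold double-significance seed threshold.
#' @param window_kb half-window in kilobases.
#' @return tibble `chrom`, `start`, `end`, `n_seeds`; zero rows when no
#'   variant passes.
#' @export
select_regions <- function(gwas1, gwas2, p_threshold = 1e-6, window_kb = 250) {
  seeds <- inner_join(
    gwas1 %>% filter(!is.na(.data$pval), .data$pval < p_threshold) %>%
      select("variant_id", "chrom", "pos"),
    gwas2 %>% filter(!is.na(.data$pval), .data$pval < p_threshold) %>%
      select("variant_id"),
    by = "variant_id"
  )
  if (nrow(seeds) == 0) {
    return(tibble(chrom = integer(), start = integer(), end = integer(),
                  n_seeds = integer()))
  }
  win <- as.integer(window_kb * 1000)
  # half-open at the left so each region spans exactly 2 * win positions
  seeds %>%
    mutate(start = pmax(1L, .data$pos - win + 1L), end = .data$pos + win) %>%
    arrange(.data$chrom, .data$start) %>%
    group_by(.data$chrom) %>%
    mutate(grp = cumsum(.data$start > dplyr::lag(cummax(.data$end),
                                                 default = -1L))) %>%
    group_by(.data$chrom, .data$grp) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              n_seeds = dplyr::n(), .groups = "drop") %>%
    select("chrom", "start", "end", "n_seeds")
}

#' Restrict summary statistics to a region
#'
#' @param sumstats a `summary_stats` tibble.
#' @param chrom,start,end 1-based inclusive region bounds.
#' @return the subset, preserving class.
#' @export
region_stats <- function(sumstats, chrom, start, end) {
  sumstats %>%
    filter(.data$chrom == !!chrom, .data$pos >= start, .data$pos <= end)
}
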