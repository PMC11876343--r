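#' Read a PGS-Catalog-style weight file
#'
#' Tab-separated with a header and optional `#`-prefixed metadata lines.
#' Accepts `rsID` or `variant_id` for the variant column and
#' `effect_weight` or `weight` for the weight column; `other_allele` and
#' `allelefrequency_effect` (renamed `eaf`) are optional.
#'
#' @param path file path.
#' @param score_id label for the score; defaults to the file name.
#' @return a weight-set tibble: `variant_id`, `effect_allele`,
#'   `other_allele`, `weight`, optional `eaf`, `score_id`.
#' @export
read_pgs_weights <- function(path, score_id = NULL) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  nm <- names(tab)
  pick <- function(...) {
    cand <- c(...)
    hit <- cand[cand %in% nm]
    if (length(hit) == 0) stop("weight file lacks column(s): ",
                               paste(cand, collapse = "/"), call. = FALSE)
    hit[1]
  }
  out <- tibble(
    variant_id = as.character(tab[[pick("variant_id", "rsID", "rsid")]]),
    effect_allele = as.character(tab[[pick("effect_allele")]]),
    other_allele = if (any(c("other_allele", "reference_allele") %in% nm))
      as.character(tab[[pick("other_allele", "reference_allele")]]) else NA_character_,
    weight = as.numeric(tab[[pick("effect_weight", "weight")]])
  )
  if ("allelefrequency_effect" %in% nm) out$eaf <- as.numeric(tab$allelefrequency_effect)
  out$score_id <- score_id %||% sub("\\.[^.]*$", "", basename(path))
  validate_weightset(out)
  out
}

validate_weightset <- function(w) {
  check_that(all(c("variant_id", "effect_allele", "weight") %in% names(w)),
             "weight set needs variant_id, effect_allele, weight columns")
  check_that(!anyDuplicated(w$variant_id), "duplicate variant_ids in weight set")
  check_that(all(is.finite(w$weight)), "non-finite weights")
  invisible(w)
}

#' Compute a polygenic score from allele-dosage data
#'
#' `score_i = sum_j w_j * d_ij` where `d_ij` is the dosage of the weight's
#' effect allele: when the weight's effect allele equals the matrix's
#' *other* allele (and vice versa) the dosage is flipped to `2 - d`.
#' Variants whose allele pair cannot be reconciled with the matrix are
#' dropped (counted in attribute `n_allele_dropped`, with a warning).
#' Weight variants absent from the matrix are handled by `missing_policy`:
#' `"drop"` contributes nothing; `"mean_impute"` contributes
#' `w * 2 * eaf`, requiring an `eaf` column in the weight set. `NA`
#' dosages inside the matrix contribute 0 under `"drop"` and the column
#' mean under `"mean_impute"`.
#'
#' @param genotypes a `genotype_matrix`.
#' @param weights a weight-set tibble (see [read_pgs_weights()]).
#' @param missing_policy `"drop"` (default) or `"mean_impute"`.
#' @param reference optional logical/integer index of the reference stratum
#'   used to standardize; default all samples.
#' @return a tibble `sample_id`, `score` (raw), `score_std` (mean 0, SD 1
#'   in the reference stratum). Attributes: `n_used`, `n_missing`,
#'   `n_allele_dropped`, `score_id`.
#' @export
compute_pgs <- function(genotypes, weights, missing_policy = c("drop", "mean_impute"),
                        reference = NULL) {
  missing_policy <- match.arg(missing_policy)
  validate_weightset(weights)
  v <- genotypes$variants
  idx <- match(weights$variant_id, v$variant_id)
  present <- !is.na(idx)
  check_that(any(present), "no overlap between weight set and genotype matrix")

  wp <- weights[present, , drop = FALSE]
  vm <- v[idx[present], , drop = FALSE]
  same <- wp$effect_allele == vm$effect_allele &
    (is.na(wp$other_allele) | wp$other_allele == vm$other_allele)
  flipped <- wp$effect_allele == vm$other_allele &
    (is.na(wp$other_allele) | wp$other_allele == vm$effect_allele)
  usable <- same | flipped
  n_allele_dropped <- sum(!usable)
  if (n_allele_dropped > 0) {
    warning(sprintf("%d weight variant(s) dropped: irreconcilable alleles",
                    n_allele_dropped), call. = FALSE)
  }

  D <- dosage_cols(genotypes, wp$variant_id[usable])
  if (anyNA(D)) {
    if (missing_policy == "mean_impute") {
      cm <- colMeans(D, na.rm = TRUE)
      for (j in seq_len(ncol(D))) D[is.na(D[, j]), j] <- cm[j]
    } else {
      D[is.na(D)] <- 0
    }
  }
  wv <- wp$weight[usable]
  fl <- flipped[usable]
  # flipped variants score 2 - d: constant offset 2*w plus negated weight
  score <- drop(D %*% ifelse(fl, -wv, wv)) + sum(2 * wv[fl])

  n_missing <- sum(!present)
  if (n_missing > 0 && missing_policy == "mean_impute") {
    check_that("eaf" %in% names(weights) &&
                 all(is.finite(weights$eaf[!present])),
               "mean_impute for absent variants requires an `eaf` column")
    score <- score + sum(weights$weight[!present] * 2 * weights$eaf[!present])
  }

  ref <- reference %||% seq_along(score)
  mu <- mean(score[ref])
  sig <- sd(score[ref])
  out <- tibble(
    sample_id = genotypes$sample_ids,
    score = score,
    score_std = if (is.finite(sig) && sig > 0) (score - mu) / sig else score * 0
  )
  attr(out, "n_used") <- sum(usable)
  attr(out, "n_missing") <- n_missing
  attr(out, "n_allele_dropped") <- n_allele_dropped
  attr(out, "score_id") <- weights$score_id[1] %||% "score"
  out
}

#' Clumping parameters
#'
#' Defaults follow the standard GWAS-significant selection: p < 5e-8,
#' r-squared < 0.1 within a 250 kb window around each index variant. The
#' reverse-MR instrument selection uses `clump_params(5e-8, 0.001, 500)`.
#'
#' @param p_threshold index-variant p-value threshold in `(0, 1]`.
#' @param r2_threshold squared dosage correlation above which neighbours
#'   are claimed, in `(0, 1]`.
#' @param window_kb half-window in kilobases (inclusive at both ends).
#' @return list of class `clump_params`.
#' @export
clump_params <- function(p_threshold = 5e-8, r2_threshold = 0.1, window_kb = 250) {
  check_number(p_threshold, "p_threshold", lower = 0, upper = 1, open_lower = TRUE)
  check_number(r2_threshold, "r2_threshold", lower = 0, upper = 1, open_lower = TRUE)
  check_number(window_kb, "window_kb", lower = 0, open_lower = TRUE)
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb), class = "clump_params")
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly takes the smallest-p unclaimed variant passing
#' `p_threshold` as an index variant and claims every unclaimed variant on
#' the same chromosome within `window_kb` kb (inclusive) whose dosage
#' r-squared with the index exceeds `r2_threshold`. Ties on p are broken
#' by lexicographically smaller `variant_id`, making the output
#' independent of input row order. If nothing passes the threshold an
#' empty weight set is returned (not an error).
#'
#' @param sumstats a `summary_stats` tibble.
#' @param ld_source a `genotype_matrix` supplying dosages for r-squared.
#' @param params a [clump_params()].
#' @param score_id label for the derived weight set.
#' @return a weight-set tibble whose weights are the index variants'
#'   betas.
#' @export
clump <- function(sumstats, ld_source, params = clump_params(),
                  score_id = "clumped") {
  check_that(inherits(params, "clump_params"), "`params` must be clump_params")
  ss <- sumstats %>%
    filter(!is.na(.data$pval), .data$pval < params$p_threshold) %>%
    arrange(.data$pval, .data$variant_id)
  if (nrow(ss) == 0) {
    return(tibble(variant_id = character(), effect_allele = character(),
                  other_allele = character(), weight = numeric(),
                  score_id = character()))
  }
  check_that(all(ss$variant_id %in% colnames(ld_source$dosages)),
             "sumstats variants missing from the LD source")
  D <- dosage_cols(ld_source, ss$variant_id)

  claimed <- rep(FALSE, nrow(ss))
  keep <- integer(0)
  win <- params$window_kb * 1000
  for (i in seq_len(nrow(ss))) {
    if (claimed[i]) next
    keep <- c(keep, i)
    claimed[i] <- TRUE
    near <- which(!claimed &
                    ss$chrom == ss$chrom[i] &
                    abs(ss$pos - ss$pos[i]) <= win)
    if (length(near) > 0) {
      r2 <- suppressWarnings(cor(D[, i], D[, near, drop = FALSE]))^2
      r2[is.na(r2)] <- 0
      claimed[near[r2[1, ] > params$r2_threshold]] <- TRUE
    }
  }
  ss %>%
    slice(keep) %>%
    mutate(weight = .data$beta, score_id = score_id) %>%
    select("variant_id", "effect_allele", "other_allele", "weight", "score_id")
}

#' Validate a polygenic score against its target trait
#'
#' Per-SD association of the standardized score with a quantitative
#' (linear model) or binary (logistic model) outcome, adjusting for
#' covariates.
#'
#' @param score a score tibble from [compute_pgs()] or a numeric vector.
#' @param outcome numeric vector; binary 0/1 triggers a logistic fit.
#' @param covariates optional data frame.
#' @return one-row tibble: `estimate` (per SD), `se`, `statistic`, `pval`,
#'   `n`, `model` (`"linear"` or `"logistic"`).
#' @export
validate_pgs <- function(score, outcome, covariates = NULL) {
  s <- if (is.data.frame(score)) score$score_std else as.numeric(score)
  check_that(length(s) == length(outcome), "score/outcome length mismatch")
  check_that(var(outcome) > 0, "outcome is constant (degenerate)")
  s <- standardize(s, "score")
  binary <- all(outcome %in% c(0, 1))
  X <- covariate_design(covariates, length(s))
  dat <- data.frame(.y = outcome, .s = s, X[, -1, drop = FALSE])
  form <- as.formula(paste(".y ~ .s", if (ncol(X) > 1)
    paste("+", paste(colnames(X)[-1], collapse = " + ")) else ""))
  if (binary) {
    fit <- glm(form, data = dat, family = binomial())
    co <- unname(summary(fit)$coefficients[".s", ])
    tibble(estimate = co[1], se = co[2], statistic = co[3], pval = co[4],
           n = length(s), model = "logistic")
  } else {
    fit <- lm(form, data = dat)
    co <- unname(summary(fit)$coefficients[".s", ])
    tibble(estimate = co[1], se = co[2], statistic = co[3], pval = co[4],
           n = length(s), model = "linear")
  }
}
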