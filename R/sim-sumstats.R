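#' Per-variant GWAS summary statistics with covariate adjustment
#'
#' Computes marginal (one-variant-at-a-time) association statistics for a
#' quantitative or binary phenotype. Quantitative traits use least squares
#' via Frisch-Waugh residualization (numerically identical to fitting
#' `lm(y ~ dosage + covariates)` per variant, but vectorised); binary
#' traits fit a per-variant logistic regression. Effect-allele frequency is
#' exactly the column mean dosage divided by 2. P-values use the normal
#' approximation `2 * pnorm(-|beta/se|)` so they are exactly consistent
#' with the reported beta and SE.
#'
#' Zero-variance variants are emitted with `beta`, `se`, and `pval` set to
#' `NA` (undefined) and are excluded by all downstream consumers.
#'
#' @param genotypes a `genotype_matrix` (already subset to the analysis
#'   samples; see [subset_samples()]).
#' @param phenotype numeric vector, one value per sample; binary 0/1 for
#'   `trait_type = "cc"`.
#' @param covariates optional data frame of numeric covariates.
#' @param trait_type `"quant"` or `"cc"`.
#' @param variant_ids optional subset of variants to test.
#' @return a `summary_stats` tibble: `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`,
#'   `trait_type`, `case_prop`.
#' @export
compute_summary_stats <- function(genotypes, phenotype, covariates = NULL,
                                  trait_type = c("quant", "cc"),
                                  variant_ids = NULL) {
  trait_type <- match.arg(trait_type)
  check_that(inherits(genotypes, "genotype_matrix"),
             "`genotypes` must be a genotype_matrix")
  n <- nrow(genotypes$dosages)
  check_that(length(phenotype) == n,
             "phenotype length (%d) != sample count (%d)", length(phenotype), n)
  check_that(all(is.finite(phenotype)), "phenotype has non-finite values")
  if (trait_type == "cc") {
    check_that(all(phenotype %in% c(0, 1)), "cc phenotype must be 0/1")
  }

  vtab <- genotypes$variants
  if (!is.null(variant_ids)) {
    vtab <- vtab[match(variant_ids, vtab$variant_id), , drop = FALSE]
    check_that(!anyNA(vtab$variant_id), "unknown variant ids requested")
  }
  G <- dosage_cols(genotypes, vtab$variant_id)
  X <- covariate_design(covariates, n)

  if (trait_type == "quant") {
    res <- gwas_quant(G, phenotype, X)
  } else {
    res <- gwas_logistic(G, phenotype, X)
  }

  tibble(
    variant_id = vtab$variant_id,
    chrom = vtab$chrom,
    pos = vtab$pos,
    effect_allele = vtab$effect_allele,
    other_allele = vtab$other_allele,
    eaf = unname(colMeans(G) / 2),
    beta = res$beta,
    se = res$se,
    pval = ifelse(is.na(res$se), NA_real_, p_normal(res$beta, res$se)),
    n = n,
    trait_type = .env$trait_type,
    case_prop = if (.env$trait_type == "cc") mean(phenotype) else NA_real_
  ) %>% structure(class = c("summary_stats", class(tibble())))
}

# intercept + covariate design matrix
covariate_design <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0)) {
    return(matrix(1, nrow = n, ncol = 1))
  }
  covariates <- as.data.frame(covariates)
  check_that(nrow(covariates) == n, "covariate rows != sample count")
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  check_that(all(is.finite(X)), "covariates contain non-finite values")
  X
}

# Vectorised per-variant least squares after projecting out X from both
# sides (Frisch-Waugh-Lovell); df = n - ncol(X) - 1.
gwas_quant <- function(G, y, X) {
  qx <- qr(X)
  ry <- qr.resid(qx, y)
  rg <- qr.resid(qx, G)
  gg <- colSums(rg^2)
  gy <- drop(crossprod(rg, ry))
  ok <- gg > 1e-12
  beta <- unname(ifelse(ok, gy / gg, NA_real_))
  df <- nrow(G) - ncol(X) - 1L
  rss <- pmax(0, sum(ry^2) - ifelse(ok, beta^2 * gg, 0))
  se <- unname(ifelse(ok, sqrt(rss / df / gg), NA_real_))
  list(beta = beta, se = se)
}

# Per-variant logistic fit (variant + covariates); returns the variant term.
gwas_logistic <- function(G, y, X) {
  m <- ncol(G)
  beta <- se <- rep(NA_real_, m)
  start <- NULL
  for (j in seq_len(m)) {
    g <- G[, j]
    if (var(g) < 1e-12) next
    Xj <- cbind(X, dosage = g)
    fit <- suppressWarnings(
      glm.fit(Xj, y, family = binomial(), start = start,
              control = list(epsilon = 1e-9, maxit = 50))
    )
    cf <- fit$coefficients
    w <- fit$weights
    # Wald SE from the weighted information matrix
    XtWX <- crossprod(Xj * sqrt(w))
    V <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    if (is.null(V)) next
    k <- ncol(Xj)
    beta[j] <- unname(cf[k])
    se[j] <- unname(sqrt(V[k, k]))
    if (is.null(start)) start <- c(cf[-k], 0)
  }
  list(beta = beta, se = se)
}

#' Subset a genotype matrix by sample
#'
#' @param genotypes a `genotype_matrix`.
#' @param keep logical or integer index, or a character vector of sample
#'   ids.
#' @return a `genotype_matrix` restricted to the requested samples.
#' @export
subset_samples <- function(genotypes, keep) {
  check_that(inherits(genotypes, "genotype_matrix"),
             "`genotypes` must be a genotype_matrix")
  if (is.character(keep)) keep <- match(keep, genotypes$sample_ids)
  check_that(!anyNA(keep), "unknown sample ids")
  genotypes$dosages <- genotypes$dosages[keep, , drop = FALSE]
  genotypes$sample_ids <- genotypes$sample_ids[keep]
  genotypes
}

#' Protein-wise quantitative GWAS over a shared covariate projection
#'
#' Runs [compute_summary_stats()] for many protein columns at once,
#' sharing the covariate residualization across traits.
#'
#' @param genotypes a `genotype_matrix` subset to the analysis samples.
#' @param cohort matching cohort rows holding the protein columns.
#' @param protein_ids character vector of protein column names.
#' @param covariates data frame of covariates (same rows).
#' @param variant_ids optional variant subset.
#' @return named list of `summary_stats` tibbles, one per protein.
#' @export
protein_gwas <- function(genotypes, cohort, protein_ids, covariates = NULL,
                         variant_ids = NULL) {
  n <- nrow(genotypes$dosages)
  check_that(nrow(cohort) == n, "cohort rows != genotype samples")
  vtab <- genotypes$variants
  if (!is.null(variant_ids)) vtab <- vtab[match(variant_ids, vtab$variant_id), ]
  G <- dosage_cols(genotypes, vtab$variant_id)
  X <- covariate_design(covariates, n)
  qx <- qr(X)
  rg <- qr.resid(qx, G)
  gg <- colSums(rg^2)
  ok <- gg > 1e-12
  df <- n - ncol(X) - 1L
  eaf <- unname(colMeans(G) / 2)

  out <- lapply(protein_ids, function(pid) {
    ry <- qr.resid(qx, cohort[[pid]])
    gy <- drop(crossprod(rg, ry))
    beta <- unname(ifelse(ok, gy / gg, NA_real_))
    rss <- pmax(0, sum(ry^2) - ifelse(ok, beta^2 * gg, 0))
    se <- unname(ifelse(ok, sqrt(rss / df / gg), NA_real_))
    tibble(
      variant_id = vtab$variant_id, chrom = vtab$chrom, pos = vtab$pos,
      effect_allele = vtab$effect_allele, other_allele = vtab$other_allele,
      eaf = eaf, beta = beta, se = se,
      pval = ifelse(is.na(se), NA_real_, p_normal(beta, se)),
      n = n, trait_type = "quant", case_prop = NA_real_
    ) %>% structure(class = c("summary_stats", class(tibble())))
  })
  names(out) <- protein_ids
  out
}
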