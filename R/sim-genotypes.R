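#' Simulate genotype dosages with within-region LD
#'
#' Haplotypes within a region follow a first-order Markov chain on allele
#' state: each region draws a single minor-allele frequency from
#' `maf_range`, the first variant's allele is Bernoulli(MAF), and each
#' subsequent allele copies its neighbour with probability `ld_rho`
#' (otherwise an independent Bernoulli(MAF) draw). This yields marginal
#' frequency MAF at every variant and an exact AR(1) correlation
#' `ld_rho^d` between variants `d` apart, on haplotypes and therefore on
#' dosages. Regions are mutually independent. Layout: protein `p` owns a
#' cis region on chromosome `p` (TSS at 1 Mb, variants every 4 kb);
#' polygenic-score variants sit on one extra chromosome, 2 Mb apart, each
#' its own region.
#'
#' @param config a [sim_config()].
#' @return an object of class `genotype_matrix`: a list with `dosages`
#'   (samples x variants matrix, values in `[0, 2]`), `variants` (tibble
#'   with `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `maf`, `region`, `protein_id`), and `sample_ids`.
#' @export
#' @examples
#' g <- simulate_genotypes(sim_config(n_proteins = 2, n_discovery = 100,
#'   n_replication = 50, n_gwas_exposure = 50, n_gwas_outcome = 50))
#' dim(g$dosages)
simulate_genotypes <- function(config) {
  check_that(inherits(config, "sim_config"), "`config` must be a sim_config")
  n <- total_samples(config)
  set.seed(derive_seed(config$seed, "genotypes"))

  m_cis <- config$n_variants_per_cis_region
  regions <- list()
  variant_rows <- list()
  for (p in seq_len(config$n_proteins)) {
    regions[[p]] <- list(m = as.integer(m_cis),
                         maf = runif(1, config$maf_range[1], config$maf_range[2]))
    variant_rows[[p]] <- tibble(
      variant_id = sprintf("cis%02d_v%02d", p, seq_len(m_cis)),
      chrom = p,
      pos = 1000000L + (seq_len(m_cis) - 1L) * 4000L,
      region = sprintf("cis%02d", p),
      protein_id = sprintf("protein_%02d", p)
    )
  }
  pgs_chrom <- config$n_proteins + 1L
  for (j in seq_len(config$pgs_n_variants)) {
    k <- config$n_proteins + j
    regions[[k]] <- list(m = 1L, maf = runif(1, config$maf_range[1], config$maf_range[2]))
    variant_rows[[k]] <- tibble(
      variant_id = sprintf("pgs_v%03d", j),
      chrom = pgs_chrom,
      pos = 1000000L + (j - 1L) * 2000000L,
      region = sprintf("pgs%03d", j),
      protein_id = NA_character_
    )
  }
  variants <- bind_rows(variant_rows)
  variants$effect_allele <- "A"
  variants$other_allele <- "G"
  variants$maf <- rep(vapply(regions, function(r) r$maf, numeric(1)),
                      vapply(regions, function(r) r$m, integer(1)))
  variants <- variants[, c("variant_id", "chrom", "pos", "effect_allele",
                           "other_allele", "maf", "region", "protein_id")]

  m_total <- nrow(variants)
  dosages <- matrix(0L, nrow = n, ncol = m_total,
                    dimnames = list(NULL, variants$variant_id))
  col0 <- 0L
  for (r in regions) {
    block <- sim_region_haplotypes(n, r$m, r$maf, config$ld_rho) +
      sim_region_haplotypes(n, r$m, r$maf, config$ld_rho)
    dosages[, col0 + seq_len(r$m)] <- block
    col0 <- col0 + r$m
  }

  structure(
    list(dosages = dosages,
         variants = variants,
         sample_ids = sprintf("S%06d", seq_len(n))),
    class = "genotype_matrix"
  )
}

# One haplotype block: n x m matrix of 0/1 alleles, Markov chain across
# columns with copy probability rho and marginal frequency maf.
sim_region_haplotypes <- function(n, m, maf, rho) {
  h <- matrix(0L, nrow = n, ncol = m)
  h[, 1] <- rbinom(n, 1L, maf)
  if (m > 1L) {
    for (j in 2:m) {
      copy <- rbinom(n, 1L, rho)
      fresh <- rbinom(n, 1L, maf)
      h[, j] <- copy * h[, j - 1L] + (1L - copy) * fresh
    }
  }
  h
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%d regions)\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$variants$region))))
  invisible(x)
}

# Dosage columns for a set of variant ids, in the requested order.
dosage_cols <- function(genotypes, variant_ids) {
  idx <- match(variant_ids, colnames(genotypes$dosages))
  check_that(!anyNA(idx), "variant ids missing from the genotype matrix")
  genotypes$dosages[, idx, drop = FALSE]
}
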