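# Shared small-scale fixtures, built once per test run.

small_config <- function(seed = 101, ...) {
  sim_config(
    n_discovery = 1500, n_replication = 800, n_gwas_exposure = 800,
    n_gwas_outcome = 1200, n_proteins = 12, n_pgs_targets = 3,
    n_causal_proteins = 3, n_reverse_proteins = 0, n_coloc_distinct = 2,
    pgs_n_variants = 10, seed = seed, ...
  )
}

# one cached cohort reused by read-only tests
.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- small_config()
    g <- simulate_genotypes(cfg)
    sim <- simulate_cohort(cfg, g)
    .fixture_env$sim <- list(config = cfg, genotypes = g,
                             cohort = sim$cohort, truth = sim$truth)
  }
  .fixture_env$sim
}

# Deterministic toy genotype matrix with explicit dosage columns.
toy_genotypes <- function(dosages, chrom = NULL, pos = NULL,
                          effect = "A", other = "G") {
  m <- ncol(dosages)
  structure(list(
    dosages = dosages,
    variants = tibble::tibble(
      variant_id = colnames(dosages),
      chrom = chrom %||% rep(1L, m),
      pos = pos %||% (1000L + seq_len(m)),
      effect_allele = rep_len(effect, m),
      other_allele = rep_len(other, m),
      maf = pmin(colMeans(dosages) / 2, 1 - colMeans(dosages) / 2),
      region = "toy", protein_id = NA_character_
    ),
    sample_ids = sprintf("S%03d", seq_len(nrow(dosages)))
  ), class = "genotype_matrix")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force BH step-up definition: q_i = min_{j >= i} p_(j) * m / j.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
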