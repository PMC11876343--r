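#' Instrument annotation from a truth ledger and genotype layout
#'
#' Builds the variant-to-protein annotation the instrument QC consumes:
#' `n_proteins_hit` counts the distinct proteins each variant truly
#' affects (cis effects and the trans hub alike) and `cis_protein` names
#' the protein whose cis region (within 1 Mb of the TSS) the variant
#' falls in.
#'
#' @param truth a `truth_ledger`.
#' @param genotypes the matching `genotype_matrix`.
#' @return tibble `variant_id`, `n_proteins_hit`, `cis_protein`.
#' @export
instrument_annotation <- function(truth, genotypes) {
  hits <- truth$variants %>%
    filter(.data$beta_protein != 0) %>%
    distinct(.data$variant_id, .data$protein_id) %>%
    dplyr::count(.data$variant_id, name = "n_proteins_hit")
  genotypes$variants %>%
    select("variant_id", cis_protein = "protein_id") %>%
    left_join(hits, by = "variant_id") %>%
    mutate(n_proteins_hit = ifelse(is.na(.data$n_proteins_hit), 0L,
                                   .data$n_proteins_hit)) %>%
    select("variant_id", "n_proteins_hit", "cis_protein")
}

#' Proteome-wide two-sample MR scan
#'
#' For each protein: selects instruments by clumping its pQTL summary
#' statistics, harmonizes them with the outcome GWAS, applies the
#' instrument QC (F >= `f_min`, pQTLs hitting more than `pleiotropy_max`
#' proteins removed, >= `min_cis` cis instruments in cis-only mode), runs
#' the four conventional estimators, and collects the median-p consensus
#' with the Egger pleiotropy gate.
#'
#' @param protein_sumstats named list of protein `summary_stats`.
#' @param outcome_sumstats outcome-trait `summary_stats`.
#' @param ld_source `genotype_matrix` used for clumping r-squared.
#' @param annotation tibble from [instrument_annotation()] (optional; QC
#'   columns are skipped when absent).
#' @param params instrument-selection [clump_params()].
#' @param cis_only restrict to cis instruments with the minimum-count
#'   gate.
#' @param f_min,pleiotropy_max,min_cis QC thresholds, see
#'   [instrument_qc()].
#' @param n_boot,seed median-bootstrap controls.
#' @return list with `consensus` (an `mr_consensus` tibble), `fits`
#'   (per-method rows), and `skips` (tibble of skipped proteins with
#'   reasons).
#' @export
mr_scan <- function(protein_sumstats, outcome_sumstats, ld_source,
                    annotation = NULL, params = clump_params(),
                    cis_only = TRUE, f_min = 10, pleiotropy_max = 4,
                    min_cis = 3, n_boot = 1000, seed = 1) {
  skips <- list()
  fits <- purrr::imap_dfr(protein_sumstats, function(ss, pid) {
    iv <- clump(ss, ld_source, params)
    if (nrow(iv) == 0) {
      skips[[pid]] <<- "no genome-wide-significant pQTLs"
      return(NULL)
    }
    exp_iv <- ss %>% filter(.data$variant_id %in% iv$variant_id)
    ann <- NULL
    if (!is.null(annotation)) {
      ann <- annotation %>%
        mutate(is_cis = !is.na(.data$cis_protein) & .data$cis_protein == pid) %>%
        select("variant_id", "n_proteins_hit", "is_cis")
    }
    instr <- tryCatch(harmonize(exp_iv, outcome_sumstats, annotation = ann),
                      error = function(e) NULL)
    if (is.null(instr) || nrow(instr) == 0) {
      skips[[pid]] <<- "no harmonizable instruments"
      return(NULL)
    }
    instr <- instrument_qc(instr, f_min = f_min,
                           pleiotropy_max = pleiotropy_max,
                           min_cis = min_cis, cis_only = cis_only)
    if (isTRUE(attr(instr, "skip")) || nrow(instr) == 0) {
      skips[[pid]] <<- attr(instr, "skip_reason") %||% "no instruments after QC"
      return(NULL)
    }
    mr_all(instr, n_boot = n_boot, seed = seed) %>%
      mutate(protein_id = pid, .before = 1)
  })
  skip_tbl <- tibble(protein_id = names(skips),
                     reason = unlist(skips) %||% character(0))
  if (nrow(fits) == 0) {
    return(list(consensus = NULL, fits = NULL, skips = skip_tbl))
  }
  list(consensus = consensus(fits), fits = fits, skips = skip_tbl)
}
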