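#' Read a GMT pathway file
#'
#' Tab-separated lines: pathway id, description, then member ids.
#'
#' @param path file path.
#' @return named list of character member vectors; descriptions kept in
#'   attribute `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(out) <- vapply(fields, `[[`, character(1), 1)
  attr(out, "description") <- vapply(fields, `[[`, character(1), 2)
  out
}

#' Background-restricted pathway over-representation
#'
#' One-sided hypergeometric enrichment of a hit set against a pathway
#' collection, with the statistical domain restricted to the assayed
#' background: every pathway is intersected with `background` before
#' testing, pathways with no background members are skipped, and the
#' upper-tail p-value is `P[X >= k]` for population size `N = |background|`,
#' `K` pathway members in the background, and `n = |hits|` draws. BH FDR
#' is applied across the tested pathways.
#'
#' @param hits character vector, a subset of `background` (enforced).
#' @param background character vector defining the statistical domain.
#' @param pathways named list of member-id vectors (see [read_gmt()] or
#'   [simulate_pathways()]).
#' @return tibble `pathway_id`, `k`, `K`, `n`, `N`, `pval`, `qval`,
#'   ordered by p-value.
#' @export
enrich <- function(hits, background, pathways) {
  hits <- unique(hits)
  background <- unique(background)
  check_that(all(hits %in% background),
             "hits must be contained in the background (%d outside)",
             sum(!hits %in% background))
  n_bg <- length(background)
  n_hit <- length(hits)

  rows <- purrr::imap_dfr(pathways, function(members, pid) {
    in_bg <- intersect(unique(members), background)
    bigK <- length(in_bg)
    if (bigK == 0) return(NULL)
    k <- length(intersect(in_bg, hits))
    # upper tail P[X >= k]; phyper(k-1, ...) with lower.tail = FALSE
    p <- phyper(k - 1, bigK, n_bg - bigK, n_hit, lower.tail = FALSE)
    tibble(pathway_id = pid, k = k, K = bigK, n = n_hit, N = n_bg,
           pval = min(1, p))
  })
  if (nrow(rows) == 0) {
    return(tibble(pathway_id = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), pval = numeric(),
                  qval = numeric()))
  }
  rows %>%
    mutate(qval = bh_fdr(.data$pval)) %>%
    arrange(.data$pval)
}
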