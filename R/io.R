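# TSV readers/writers for the pipeline's interchange formats. All files
# are plain text with a header row.

#' Write and read GWAS summary statistics
#'
#' Columns, in order: `variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`, `trait_type`,
#' `case_prop`.
#'
#' @param sumstats a `summary_stats` tibble.
#' @param path file path.
#' @return `write_sumstats()` returns `path` invisibly; `read_sumstats()`
#'   returns a `summary_stats` tibble.
#' @export
write_sumstats <- function(sumstats, path) {
  cols <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pval", "n", "trait_type", "case_prop")
  readr::write_tsv(sumstats[, cols], path)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    variant_id = "c", chrom = "i", pos = "i",
                    effect_allele = "c", other_allele = "c",
                    eaf = "d", beta = "d", se = "d", pval = "d",
                    n = "i", trait_type = "c", case_prop = "d")) %>%
    structure(class = c("summary_stats", class(tibble())))
}

#' Write a genotype matrix as dosage + variant annotation TSVs
#'
#' @param genotypes a `genotype_matrix`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisible character vector of the two paths.
#' @export
write_genotypes <- function(genotypes, dir, prefix = "geno") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dpath <- file.path(dir, paste0(prefix, "_dosages.tsv"))
  vpath <- file.path(dir, paste0(prefix, "_variants.tsv"))
  dos <- as_tibble(genotypes$dosages)
  dos <- bind_cols(tibble(sample_id = genotypes$sample_ids), dos)
  readr::write_tsv(dos, dpath)
  readr::write_tsv(genotypes$variants, vpath)
  invisible(c(dosages = dpath, variants = vpath))
}

#' Read a genotype matrix written by [write_genotypes()]
#'
#' @param dosage_path,variant_path the two TSV paths.
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(dosage_path, variant_path) {
  dos <- readr::read_tsv(dosage_path, show_col_types = FALSE)
  variants <- readr::read_tsv(variant_path, show_col_types = FALSE)
  ids <- dos$sample_id
  m <- as.matrix(dos[, -1, drop = FALSE])
  rownames(m) <- NULL
  structure(list(dosages = m, variants = variants, sample_ids = ids),
            class = "genotype_matrix")
}

#' Serialize a truth ledger to JSON
#'
#' @param truth a `truth_ledger`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(proteins = truth$proteins, variants = truth$variants,
         globals = truth$globals),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
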