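#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes the nine stages end to end on one configuration:
#' `simulate` (genotypes, cohort, truth ledger, trial, GWAS tables),
#' `score` (polygenic scores plus a clump-derived score and validation),
#' `assoc` (two-stage scan with BMI adjustment and beta comparison),
#' `mediation` (BMI mediation of attenuated pairs), `mr` (forward
#' cis-instrument scan, MVMR with BMI, reverse MR), `coloc`
#' (truth-designated cis regions plus double-significance region
#' selection), `trial` (tiered endpoint scan, repeat-measurement modes,
#' PGS mediation), `enrich` (over-representation of the replicated set),
#' and `report`. Each stage consumes only earlier stages' outputs; a
#' stage failure is recorded in the manifest and the dependent stages are
#' skipped.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, stage outputs are
#'   written as TSV/JSON and their MD5 digests recorded in the manifest.
#' @param n_boot bootstrap replicates used by the mediation and median-MR
#'   steps (kept modest by default; estimates are deterministic).
#' @param verbose print stage progress.
#' @return a `pipeline_result`: list of stage outputs plus `manifest`
#'   (stage status/row-count/timing tibble, config echo, file digests).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         n_boot = 200, verbose = FALSE) {
  check_that(inherits(config, "sim_config"), "`config` must be a sim_config")
  res <- list(config = config)
  manifest <- list()
  failed <- FALSE

  run_stage <- function(name, rows_of, fun) {
    if (failed) {
      manifest[[name]] <<- tibble(stage = name, status = "skipped",
                                  n_rows = NA_integer_, seconds = 0,
                                  reason = "upstream failure")
      return(invisible(NULL))
    }
    if (verbose) message("stage: ", name)
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e) structure(list(), failure = conditionMessage(e)))
    secs <- proc.time()[["elapsed"]] - t0
    if (!is.null(attr(out, "failure"))) {
      failed <<- TRUE
      manifest[[name]] <<- tibble(stage = name, status = "failed",
                                  n_rows = NA_integer_, seconds = secs,
                                  reason = attr(out, "failure"))
    } else {
      res[[name]] <<- out
      manifest[[name]] <<- tibble(stage = name, status = "ok",
                                  n_rows = rows_of(out), seconds = secs,
                                  reason = NA_character_)
    }
    invisible(NULL)
  }

  # --- simulate -------------------------------------------------------------
  run_stage("simulate", function(o) nrow(o$cohort), function() {
    genotypes <- simulate_genotypes(config)
    sim <- simulate_cohort(config, genotypes)
    cohort <- sim$cohort
    truth <- sim$truth
    prot_ids <- truth$proteins$protein_id

    trial <- simulate_trial(config, cohort %>% filter(.data$stratum == "replication"),
                            truth)

    exp_idx <- which(cohort$stratum == "gwas_exposure")
    out_idx <- which(cohort$stratum == "gwas_outcome")
    g_exp <- subset_samples(genotypes, exp_idx)
    g_out <- subset_samples(genotypes, out_idx)
    covs_exp <- cohort_covariates(cohort[exp_idx, ])
    covs_out <- cohort_covariates(cohort[out_idx, ])

    pqtl <- protein_gwas(g_exp, cohort[exp_idx, ], prot_ids, covs_exp)
    disease_gwas <- compute_summary_stats(
      g_out, cohort$incident_disease[out_idx], covs_out, trait_type = "cc")
    bmi_gwas <- compute_summary_stats(
      g_out, cohort$bmi[out_idx], covs_out, trait_type = "quant")

    list(genotypes = genotypes, cohort = cohort, truth = truth,
         trial = trial, pqtl = pqtl, disease_gwas = disease_gwas,
         bmi_gwas = bmi_gwas)
  })

  # --- score ----------------------------------------------------------------
  run_stage("score", function(o) nrow(o$scores), function() {
    sim <- res$simulate
    disc <- sim$cohort$stratum == "discovery"
    weights_gw <- truth_weightset(sim$truth, "pgs_gw")
    s_gw <- compute_pgs(sim$genotypes, weights_gw, reference = which(disc))
    weights_clump <- clump(sim$disease_gwas, sim$genotypes,
                           clump_params(5e-8, 0.1, 250), score_id = "pgs_clump")
    scores <- tibble(sample_id = s_gw$sample_id, pgs_gw = s_gw$score_std)
    if (nrow(weights_clump) > 0) {
      s_cl <- compute_pgs(sim$genotypes, weights_clump, reference = which(disc))
      scores$pgs_clump <- s_cl$score_std
    }
    validation <- validate_pgs(
      s_gw[disc, ], sim$cohort$incident_disease[disc],
      cohort_covariates(sim$cohort[disc, ]))
    list(scores = scores, weights_clump = weights_clump,
         validation = validation)
  })

  # --- assoc ----------------------------------------------------------------
  run_stage("assoc", function(o) nrow(o$scan$discovery), function() {
    sim <- res$simulate
    cohort <- filter_prevalent(sim$cohort)
    scores <- res$score$scores
    scan <- run_scan(cohort, scores)
    adj_bmi <- adjusted_scan(cohort, scores, extra = "bmi", baseline = scan)
    beta_cmp <- compare_betas(
      scan$discovery %>% filter(.data$score_id == "pgs_gw"),
      adj_bmi$report$discovery %>% filter(.data$score_id == "pgs_gw"))
    list(scan = scan, adjusted_bmi = adj_bmi, beta_compare = beta_cmp,
         cohort_filtered = cohort)
  })

  # --- mediation ------------------------------------------------------------
  run_stage("mediation", function(o) nrow(o$bmi_mediation), function() {
    sim <- res$simulate
    cohort <- res$assoc$cohort_filtered %>%
      filter(.data$stratum %in% c("discovery", "replication")) %>%
      inner_join(res$score$scores, by = "sample_id")
    covs <- cohort_covariates(cohort)
    # BMI mediation for pairs attenuated by the BMI adjustment
    att <- res$assoc$adjusted_bmi$classification %>%
      filter(.data$status == "attenuated_to_nonsignificance",
             .data$score_id == "pgs_gw")
    cand <- head(att$protein_id, 5)
    bmi_med <- purrr::map_dfr(cand, function(pid) {
      mediate_continuous(cohort, exposure = "pgs_gw", mediator = "bmi",
                         outcome = pid, covariates = covs,
                         n_boot = max(100, n_boot),
                         seed = derive_seed(config$seed, paste0("med_", pid))) %>%
        mutate(protein_id = pid,
               class = classify_mediation(.), .before = 1)
    })
    # incident-disease mediation through the replicated proteins
    rep_prot <- res$assoc$scan$replication %>%
      filter(.data$replicated, .data$score_id == "pgs_gw") %>%
      pull(.data$protein_id)
    dis_med <- purrr::map_dfr(head(rep_prot, 3), function(pid) {
      tryCatch(
        mediate_binary(cohort, exposure = "pgs_gw", mediator = pid,
                       outcome = "incident_disease", covariates = covs,
                       n_boot = max(100, n_boot),
                       seed = derive_seed(config$seed, paste0("dmed_", pid))) %>%
          mutate(protein_id = pid, .before = 1),
        error = function(e) NULL)
    })
    list(bmi_mediation = bmi_med, disease_mediation = dis_med)
  })

  # --- mr -------------------------------------------------------------------
  run_stage("mr", function(o) {
    if (is.null(o$forward$consensus)) 0L else nrow(o$forward$consensus)
  }, function() {
    sim <- res$simulate
    ann <- instrument_annotation(sim$truth, sim$genotypes)
    seed_mr <- derive_seed(config$seed, "mr")
    forward <- mr_scan(sim$pqtl, sim$disease_gwas, sim$genotypes,
                       annotation = ann, cis_only = TRUE,
                       n_boot = max(200, n_boot), seed = seed_mr)
    # MVMR: protein + BMI as joint exposures for the forward-significant set
    mv_ids <- if (!is.null(forward$consensus)) {
      forward$consensus %>% filter(.data$significant) %>% pull(.data$protein_id)
    } else character(0)
    bmi_iv <- sim$bmi_gwas %>% filter(!is.na(.data$pval), .data$pval < 1e-4)
    mv <- purrr::map(setNames(head(mv_ids, 10), head(mv_ids, 10)), function(pid) {
      ss_p <- sim$pqtl[[pid]]
      iv_p <- clump(ss_p, sim$genotypes, clump_params())
      ids <- union(iv_p$variant_id, bmi_iv$variant_id)
      if (length(ids) < 3) return(NULL)
      tab <- tibble(variant_id = ids) %>%
        inner_join(ss_p %>% select("variant_id", beta_exposure1 = "beta",
                                   se_exposure1 = "se"), by = "variant_id") %>%
        inner_join(sim$bmi_gwas %>% select("variant_id", beta_exposure2 = "beta",
                                           se_exposure2 = "se"), by = "variant_id") %>%
        inner_join(sim$disease_gwas %>% select("variant_id", beta_outcome = "beta",
                                               se_outcome = "se"), by = "variant_id")
      if (nrow(tab) < 3) return(NULL)
      tryCatch(mvmr(tab, exposure_names = c(pid, "bmi")),
               error = function(e) NULL)
    })
    reverse <- reverse_mr(sim$disease_gwas, sim$pqtl, sim$genotypes,
                          n_boot = max(200, n_boot), seed = seed_mr)
    list(forward = forward, mvmr = mv, reverse = reverse)
  })

  # --- coloc ----------------------------------------------------------------
  run_stage("coloc", function(o) nrow(o$results), function() {
    sim <- res$simulate
    selected <- purrr::map_dfr(names(sim$pqtl), function(pid) {
      sr <- select_regions(sim$disease_gwas, sim$pqtl[[pid]])
      if (nrow(sr) > 0) sr %>% mutate(protein_id = pid, .before = 1) else NULL
    })
    cand <- sim$truth$proteins %>% filter(.data$coloc_scenario != "null")
    results <- purrr::map_dfr(cand$protein_id, function(pid) {
      chrom <- which(sim$truth$proteins$protein_id == pid)
      r1 <- region_stats(sim$disease_gwas, chrom, 1L, .Machine$integer.max)
      r2 <- region_stats(sim$pqtl[[pid]], chrom, 1L, .Machine$integer.max)
      post <- tryCatch(coloc(r1, r2), error = function(e) NULL)
      if (is.null(post)) return(NULL)
      post %>% mutate(protein_id = pid,
                      scenario = cand$coloc_scenario[cand$protein_id == pid],
                      decision = coloc_decision(post), .before = 1)
    })
    list(results = results, selected_regions = selected)
  })

  # --- trial ----------------------------------------------------------------
  run_stage("trial", function(o) nrow(o$discovery), function() {
    sim <- res$simulate
    trial <- sim$trial %>%
      left_join(res$score$scores %>% select("sample_id", "pgs_gw"),
                by = "sample_id")
    discovery <- endpoint_scan(trial, tier = "base", role = "discovery")
    hits <- discovery %>% filter(.data$significant)
    clinical <- if (nrow(hits) > 0) {
      endpoint_scan(trial, protein_ids = unique(hits$protein_id),
                    tier = "clinical", role = "discovery")
    } else NULL
    repeat_modes <- repeat_measurement_scan(
      trial, protein_ids = head(attr(sim$trial, "protein_ids"), 10),
      endpoint = "renal")
    mediation <- pgs_trial_mediation(
      trial, pgs_col = "pgs_gw",
      protein_ids = unique(hits$protein_id),
      endpoint = "mace", n_boot = max(100, n_boot),
      seed = derive_seed(config$seed, "trial_med"))
    list(trial = trial, discovery = discovery, clinical = clinical,
         repeat_modes = repeat_modes, mediation = mediation)
  })

  # --- enrich ---------------------------------------------------------------
  run_stage("enrich", function(o) nrow(o$results), function() {
    sim <- res$simulate
    universe <- sim$truth$proteins$protein_id
    hits <- res$assoc$scan$replication %>%
      filter(.data$replicated) %>% pull(.data$protein_id) %>% unique()
    pathways <- simulate_pathways(
      universe,
      enriched = sim$truth$proteins$protein_id[sim$truth$proteins$scenario == "target"],
      seed = derive_seed(config$seed, "pathways"))
    results <- if (length(hits) > 0) enrich(hits, universe, pathways) else
      tibble(pathway_id = character(), k = integer(), K = integer(),
             n = integer(), N = integer(), pval = numeric(), qval = numeric())
    list(results = results, pathways = pathways, hits = hits)
  })

  # --- report ---------------------------------------------------------------
  run_stage("report", function(o) nrow(o$score_counts), function() {
    write_report(res, out_dir = NULL)
  })

  res$manifest <- list(
    stages = bind_rows(manifest),
    seed = config$seed,
    config = unclass(config),
    created = "run_pipeline"
  )

  if (!is.null(out_dir)) {
    res$manifest$files <- write_pipeline_outputs(res, out_dir)
  }
  class(res) <- "pipeline_result"
  if (failed) {
    attr(res, "failed") <- TRUE
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$manifest$stages)
  invisible(x)
}

# Write stage outputs as TSV/JSON and return a digest table.
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(obj, name) {
    if (is.null(obj) || (is.data.frame(obj) && nrow(obj) == 0)) return(invisible(NULL))
    p <- file.path(out_dir, name)
    readr::write_tsv(as_tibble(obj), p)
    paths <<- c(paths, p)
    invisible(p)
  }
  sim <- res$simulate
  if (!is.null(sim)) {
    put(sim$cohort, "cohort.tsv")
    write_sumstats(sim$disease_gwas, file.path(out_dir, "disease_gwas.tsv"))
    paths <- c(paths, file.path(out_dir, "disease_gwas.tsv"))
    write_truth(sim$truth, file.path(out_dir, "truth_ledger.json"))
    paths <- c(paths, file.path(out_dir, "truth_ledger.json"))
    put(sim$trial, "trial.tsv")
  }
  if (!is.null(res$assoc)) {
    put(res$assoc$scan$discovery, "scan_discovery.tsv")
    put(res$assoc$scan$replication, "scan_replication.tsv")
    put(res$assoc$adjusted_bmi$classification, "scan_adjusted_bmi.tsv")
    put(res$assoc$beta_compare, "beta_compare.tsv")
  }
  if (!is.null(res$mediation)) {
    put(res$mediation$bmi_mediation, "mediation.tsv")
    put(res$mediation$disease_mediation, "mediation_disease.tsv")
  }
  if (!is.null(res$mr)) {
    put(res$mr$forward$fits, "mr_fits.tsv")
    put(res$mr$forward$consensus, "mr_consensus.tsv")
    if (!is.null(res$mr$reverse$consensus)) {
      put(res$mr$reverse$consensus, "reverse_mr.tsv")
    }
  }
  if (!is.null(res$coloc)) put(res$coloc$results, "coloc.tsv")
  if (!is.null(res$trial)) {
    put(res$trial$discovery, "endpoints_base.tsv")
    put(res$trial$clinical, "endpoints_clinical.tsv")
    put(res$trial$repeat_modes, "repeat_modes.tsv")
    put(res$trial$mediation, "trial_mediation.tsv")
  }
  if (!is.null(res$enrich)) put(res$enrich$results, "enrichment.tsv")
  if (!is.null(res$report)) {
    put(res$report$score_counts, "report_score_counts.tsv")
    put(res$report$mr_forest, "report_mr_forest.tsv")
    put(res$report$trial_hr, "report_trial_hr.tsv")
  }
  # wall-times vary between runs; the recorded manifest keeps only the
  # reproducible fields so re-runs are byte-identical
  jsonlite::write_json(res$manifest$stages[, c("stage", "status", "n_rows",
                                               "reason")],
                       file.path(out_dir, "manifest_stages.json"),
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, file.path(out_dir, "manifest_stages.json"))
  digests <- tools::md5sum(paths)
  tibble(file = basename(names(digests)), md5 = unname(digests))
}

#' Summary tables for a completed pipeline run
#'
#' Builds the reporting tables: per-score discovery/replication counts,
#' the MR forest-plot data (estimate with 95% CI per method and protein),
#' and the trial hazard-ratio table.
#'
#' @param res a `pipeline_result` (or the partial stage list during a
#'   run).
#' @param out_dir unused here; kept so the stage signature matches the
#'   writer.
#' @return list of tibbles: `score_counts`, `mr_forest`, `trial_hr`.
#' @export
write_report <- function(res, out_dir = NULL) {
  score_counts <- if (!is.null(res$assoc)) {
    disc <- res$assoc$scan$discovery %>%
      group_by(.data$score_id) %>%
      summarise(n_tested = dplyr::n(),
                n_discovery_sig = sum(.data$significant), .groups = "drop")
    repl <- res$assoc$scan$replication %>%
      group_by(.data$score_id) %>%
      summarise(n_replicated = sum(.data$replicated), .groups = "drop")
    left_join(disc, repl, by = "score_id") %>%
      mutate(n_replicated = ifelse(is.na(.data$n_replicated), 0L,
                                   .data$n_replicated))
  } else tibble(score_id = character(), n_tested = integer(),
                n_discovery_sig = integer(), n_replicated = integer())

  mr_forest <- if (!is.null(res$mr) && !is.null(res$mr$forward$fits)) {
    res$mr$forward$fits %>%
      filter(.data$method != "egger_intercept") %>%
      mutate(ci_low = .data$estimate - qnorm(0.975) * .data$se,
             ci_high = .data$estimate + qnorm(0.975) * .data$se) %>%
      select("protein_id", "method", "estimate", "se", "ci_low", "ci_high",
             "pval", "n_instruments")
  } else tibble()

  trial_hr <- if (!is.null(res$trial) && nrow(res$trial$discovery) > 0) {
    res$trial$discovery %>%
      select("protein_id", "endpoint", "tier", "hazard_ratio",
             "ci_low", "ci_high", "wald_p", "n_events", "significant")
  } else tibble()

  list(score_counts = score_counts, mr_forest = mr_forest,
       trial_hr = trial_hr)
}
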