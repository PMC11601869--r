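#' Default pipeline configuration
#'
#' Parameters for the full synthetic-data analysis pipeline
#' (simulate -> detect -> annotate -> score -> cohort), as a nested list.
#' Any entry can be overridden via `overrides` (or by a YAML file through
#' [run_pipeline()]). All parameters are validated up front against the
#' preconditions of the stage that consumes them.
#'
#' @param overrides Named list of entries to replace (nested lists are merged
#'   shallowly per stage).
#' @return Named list of stage parameter lists.
#' @export
pipeline_config <- function(overrides = list()) {
  cfg <- list(
    timecourse = list(n_genes = 2000, n_replicates = 5, n_cyclic_udu = 50,
                      n_cyclic_dud = 50, n_monotonic = 0, amplitude = 2,
                      noise_sd = 0.5),
    proteome = list(n_background = 300, n_cyclic = 16, n_replicates = 5,
                    missingness = 0.2),
    cells = list(cells_per_sample = 500, background_rate = 0.02),
    cohort = list(n_samples = 300, frac_high = 1 / 3, signature_shift = 2),
    detect = list(tau = 1, q_max = 0.05, orientations = c("UDU", "DUD")),
    score = list(alpha = 0.25),
    dip = list(n_boot = 499)
  )
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && nm %in% names(cfg)) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  d <- cfg$detect
  if (d$tau < 0) stop_config("detect.tau", "must be >= 0")
  if (d$q_max <= 0 || d$q_max > 1) stop_config("detect.q_max", "must be in (0, 1]")
  if (!all(d$orientations %in% c("UDU", "DUD"))) {
    stop_config("detect.orientations", "must be a subset of {UDU, DUD}")
  }
  if (cfg$proteome$missingness < 0 || cfg$proteome$missingness > 1) {
    stop_config("proteome.missingness", "must be in [0, 1]")
  }
  if (cfg$score$alpha < 0) stop_config("score.alpha", "must be >= 0")
  if (cfg$dip$n_boot < 1) stop_config("dip.n_boot", "must be >= 1")
  invisible(cfg)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates all four data kinds, then runs detection (cyclic genes and
#' proteins, timepoint clustering), cell annotation and composition ratios,
#' signature scoring with tertile stratification, and the cohort statistics
#' (dip test on age at diagnosis per group, Kaplan-Meier curves, log-rank,
#' Fisher exact on the age-by-group dichotomy). All outputs plus a manifest
#' (parameters, seed, package version, file checksums) are written to
#' `out_dir`; a rerun with the same seed and configuration is byte-identical.
#'
#' @param config A list from [pipeline_config()], a path to a YAML file of
#'   overrides, or `NULL` for defaults.
#' @param out_dir Output directory (created; must be empty or absent).
#' @param seed Master seed; each stage derives a named sub-seed from it.
#' @return Invisible list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = 1) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- pipeline_config(config %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- simulate ---------------------------------------------------------
  tc <- do.call(simulate_timecourse,
                c(cfg$timecourse, list(seed = stage_seed(seed, "timecourse"))))
  pr <- do.call(simulate_proteome,
                c(cfg$proteome, list(seed = stage_seed(seed, "proteome"))))
  ce <- do.call(simulate_cells,
                c(cfg$cells, list(seed = stage_seed(seed, "cells"))))
  co <- do.call(simulate_cohort,
                c(cfg$cohort, list(seed = stage_seed(seed, "cohort"))))

  write_expression_csv(tc, file.path(out_dir, "expression.csv"))
  write_proteome_csv(pr, file.path(out_dir, "proteome.csv"))
  write_mtx_counts(ce, file.path(out_dir, "cells"))
  write_cohort_tsv(co, file.path(out_dir, "cohort.tsv"))
  readr::write_tsv(tc$truth, file.path(out_dir, "timecourse_truth.tsv"))
  readr::write_tsv(pr$truth, file.path(out_dir, "proteome_truth.tsv"))

  # --- detect -----------------------------------------------------------
  stats <- transition_stats(tc)
  calls <- call_cyclic_genes(stats, tau = cfg$detect$tau,
                             q_max = cfg$detect$q_max,
                             orientations = cfg$detect$orientations)
  readr::write_tsv(calls, file.path(out_dir, "cyclic_gene_calls.tsv"))
  pcalls <- call_cyclic_proteins(pr)
  readr::write_tsv(pcalls, file.path(out_dir, "cyclic_protein_calls.tsv"))
  clust <- cluster_timepoints(timepoint_profiles(tc))
  jsonlite::write_json(clust$partition, file.path(out_dir, "partition.json"))
  if (requireNamespace("ape", quietly = TRUE)) {
    write_newick(clust, file.path(out_dir, "timepoints.nwk"))
  }

  # --- annotate ---------------------------------------------------------
  ann <- annotate_cells(ce$counts, ce$panel)
  readr::write_tsv(ann, file.path(out_dir, "annotation.tsv"))
  ratios <- composition_ratios(ann, ce$cells)
  readr::write_tsv(ratios, file.path(out_dir, "composition_ratios.tsv"))

  # --- score ------------------------------------------------------------
  gene_sets <- list(cyclic_signature = co$signature_genes)
  write_gmt(gene_sets, file.path(out_dir, "signature.gmt"))
  scores <- score_samples(co$expression, co$signature_genes,
                          alpha = cfg$score$alpha) |>
    tertile_stratify()
  readr::write_tsv(scores, file.path(out_dir, "signature_scores.tsv"))

  # --- cohort -----------------------------------------------------------
  cohort <- dplyr::left_join(co$cohort, scores, by = "sample_id")
  dip_high <- dip_test(cohort$age_years[cohort$group == "high"],
                       n_boot = cfg$dip$n_boot,
                       seed = stage_seed(seed, "dip_high"))
  dip_low <- dip_test(cohort$age_years[cohort$group == "low"],
                      n_boot = cfg$dip$n_boot,
                      seed = stage_seed(seed, "dip_low"))
  lr <- logrank_test(cohort)
  km <- lapply(split(cohort, cohort$group), function(d) {
    km_estimate(d$os_time, d$os_event)
  })
  young <- cohort$age_years <= 43
  fisher <- fisher_exact(table(factor(cohort$group, c("high", "low")),
                               factor(young, c(TRUE, FALSE))))
  results <- list(
    dip = list(high = list(dip = dip_high$statistic, p = dip_high$p_value),
               low = list(dip = dip_low$statistic, p = dip_low$p_value)),
    logrank = list(chi_square = lr$chi_square, p = lr$p_value),
    fisher_young_by_group = list(p = fisher$p_value,
                                 odds_ratio = fisher$odds_ratio),
    km_curves = lapply(km, as.data.frame)
  )
  jsonlite::write_json(results, file.path(out_dir, "cohort_results.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- manifest ---------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package = "cyclaging",
    version = as.character(utils::packageVersion("cyclaging")),
    seed = seed,
    config = cfg,
    files = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(timecourse = tc, proteome = pr, cells = ce, cohort_sim = co,
                 gene_calls = calls, protein_calls = pcalls,
                 clustering = clust, annotation = ann, ratios = ratios,
                 scores = scores, results = results, manifest = manifest))
}
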