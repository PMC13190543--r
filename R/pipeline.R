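#' Pipeline stages
#'
#' The pipeline is a set of stages communicating only through documented CSV
#' files so that any stage can be re-run in isolation: `simulate` writes a
#' synthetic dataset, `validate` fits calibration curves and computes the
#' method-validation metric grid, `quantify` produces censored,
#' creatinine-adjusted sample results with aggregates, and `stats` runs the
#' cohort statistics layer.  Every output file carries a `#`-comment
#' provenance header recording the seed, stage and package version.
#'
#' @name pipeline
NULL

#' @keywords internal
stage_provenance <- function(seed, stage) {
  c(seed = as.character(seed), stage = stage,
    neoquant = as.character(utils::packageVersion("neoquant")))
}

#' Simulate stage: write a complete synthetic dataset
#'
#' @param outdir Output directory (created if missing; refuses to overwrite
#'   an existing non-empty directory unless `overwrite = TRUE`).
#' @param seed Master seed.
#' @param config Optional `neo_sim_config` (default built from the seed).
#' @param cohorts Cohort specs for [simulate_cohort()].
#' @param n_replicates Validation replicates per level.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, the list of files written.
#' @rdname pipeline
#' @export
run_simulate_stage <- function(outdir, seed = 1L, config = NULL,
                               cohorts = NULL, n_replicates = 9,
                               overwrite = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) > 0 && !overwrite) {
    stop("output directory exists and is not empty: ", outdir, call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config)) config <- sim_config(seed = seed)
  prov <- stage_provenance(config$seed, "simulate")

  val <- simulate_validation_experiment(config, n_replicates = n_replicates)
  cal <- simulate_calibration_series(config)
  peak_areas <- dplyr::bind_rows(val$records, cal)
  coh <- if (is.null(cohorts)) {
    simulate_cohort(config)
  } else {
    simulate_cohort(config, cohorts = cohorts)
  }

  files <- c(
    peak_areas = file.path(outdir, "peak_areas.csv"),
    samples = file.path(outdir, "samples.csv"),
    concentrations = file.path(outdir, "concentrations.csv"),
    ground_truth = file.path(outdir, "ground_truth.csv")
  )
  write_table(peak_areas, files["peak_areas"], provenance = prov)
  write_table(coh$samples, files["samples"], provenance = prov)
  write_table(coh$results, files["concentrations"], provenance = prov)
  write_table(coh$truth, files["ground_truth"], provenance = prov)
  invisible(files)
}

#' Validate stage: calibration curves and the validation metric grid
#'
#' @param indir Directory holding `peak_areas.csv`.
#' @param outdir Output directory.
#' @param panel A `neo_panel`.
#' @param seed Seed recorded in provenance headers.
#' @param weighting Calibration weighting.
#' @param strict Error (nonzero exit from the CLI) when any QC level fails.
#' @rdname pipeline
#' @export
run_validate_stage <- function(indir, outdir, panel = default_panel(),
                               seed = 1L, weighting = "1/x",
                               strict = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  records <- read_peak_areas(file.path(indir, "peak_areas.csv"), panel)
  prov <- stage_provenance(seed, "validate")
  curves <- fit_calibration_set(records, weighting = weighting)
  vt <- build_validation_table(records, panel, curves)
  write_results(curves, file.path(outdir, "curves.csv"), provenance = prov)
  write_results(vt$summary, file.path(outdir, "validation_summary.csv"),
                provenance = prov)
  if (nrow(vt$qc)) {
    write_results(vt$qc, file.path(outdir, "qc_grid.csv"), provenance = prov)
  }
  midrun <- check_midrun_calibrators(records, curves)
  if (nrow(midrun)) {
    write_results(midrun, file.path(outdir, "midrun_checks.csv"),
                  provenance = prov)
  }
  failed <- (if (nrow(vt$qc)) sum(!vt$qc$pass) else 0L) +
    (if (nrow(midrun)) sum(!midrun$pass) else 0L)
  if (strict && failed > 0) {
    stop(failed, " QC check(s) failed in strict mode", call. = FALSE)
  }
  invisible(list(curves = curves, validation = vt, midrun = midrun))
}

#' Quantify stage: censoring, substitution and creatinine adjustment
#'
#' @param indir Directory holding `concentrations.csv` and `samples.csv`.
#' @param outdir Output directory.
#' @param panel A `neo_panel`.
#' @param seed Seed recorded in provenance headers.
#' @param limits Per-analyte limits tibble; defaults to the panel's practical
#'   reporting limits.
#' @rdname pipeline
#' @export
run_quantify_stage <- function(indir, outdir, panel = default_panel(),
                               seed = 1L, limits = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  results <- readr::read_csv(file.path(indir, "concentrations.csv"),
                             comment = "#", show_col_types = FALSE)
  samples <- read_samples(file.path(indir, "samples.csv"))
  if (is.null(limits)) limits <- panel_limits(panel, "pooled")
  prov <- stage_provenance(seed, "quantify")
  q <- quantify_samples(results, samples, panel, limits = limits)
  write_table(q$results, file.path(outdir, "results.csv"), provenance = prov)
  write_table(q$aggregates, file.path(outdir, "aggregates.csv"),
              provenance = prov)
  write_table(q$detects, file.path(outdir, "detects.csv"), provenance = prov)
  invisible(q)
}

#' Stats stage: descriptive summaries, trends, cohort comparison, batches
#'
#' @param indir Directory holding `results.csv`, `aggregates.csv`,
#'   `detects.csv` (from the quantify stage).
#' @param outdir Output directory.
#' @param seed Seed recorded in provenance headers.
#' @param bin_width Temporal bin width in years.
#' @param trend_cohort Cohort whose temporal trend is tested (default: the
#'   cohort with the longest collection span).
#' @rdname pipeline
#' @export
run_stats_stage <- function(indir, outdir, seed = 1L, bin_width = 2,
                            trend_cohort = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  results <- readr::read_csv(file.path(indir, "results.csv"), comment = "#",
                             show_col_types = FALSE)
  aggregates <- readr::read_csv(file.path(indir, "aggregates.csv"),
                                comment = "#", show_col_types = FALSE)
  detects <- readr::read_csv(file.path(indir, "detects.csv"), comment = "#",
                             show_col_types = FALSE)
  prov <- stage_provenance(seed, "stats")

  meta <- dplyr::distinct(results[, c("sample_id", "cohort",
                                      "collection_date", "batch_id")])
  adj_wide <- tidyr::pivot_wider(
    results[, c("sample_id", "analyte", "adjusted_conc")],
    names_from = "analyte", values_from = "adjusted_conc"
  )
  agg_wide <- tidyr::pivot_wider(
    aggregates[, c("sample_id", "aggregate", "adjusted_sum")],
    names_from = "aggregate", values_from = "adjusted_sum"
  )
  wide <- dplyr::left_join(dplyr::left_join(adj_wide, agg_wide,
                                            by = "sample_id"),
                           dplyr::left_join(meta, detects, by = "sample_id"),
                           by = "sample_id")
  value_cols <- setdiff(names(wide),
                        c("sample_id", "cohort", "collection_date",
                          "batch_id", "n_detected"))
  complete <- wide[stats::complete.cases(wide[, value_cols]), ]

  # per-cohort descriptive summaries on adjusted substituted values
  summary_rows <- list()
  for (co in unique(complete$cohort)) {
    sub <- complete[complete$cohort == co, ]
    cens <- results[results$sample_id %in% sub$sample_id, ]
    for (v in value_cols) {
      flags <- if (v %in% unique(results$analyte)) {
        cens$censoring[cens$analyte == v][match(sub$sample_id,
                                                cens$sample_id[cens$analyte == v])]
      } else NULL
      sr <- summarize_exposure(sub[[v]], flags)
      summary_rows[[length(summary_rows) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(cohort = co, variable = v), sr)
    }
  }
  summary_tab <- dplyr::bind_rows(summary_rows)
  write_results(summary_tab, file.path(outdir, "summary.csv"),
                provenance = prov)

  # temporal trends within the widest-span cohort
  spans <- tapply(as.numeric(as.Date(complete$collection_date)),
                  complete$cohort, function(x) diff(range(x)))
  if (is.null(trend_cohort)) trend_cohort <- names(which.max(spans))
  tsub <- complete[complete$cohort == trend_cohort, ]
  trend_tab <- NULL
  if (nrow(tsub) >= 4) {
    anchor <- as.integer(format(min(as.Date(tsub$collection_date)), "%Y"))
    bins <- assign_temporal_bins(tsub$collection_date, width = bin_width,
                                 anchor_year = anchor)
    if (length(unique(bins)) >= 2) {
      trend_tab <- dplyr::bind_rows(lapply(value_cols, function(v) {
        dplyr::bind_cols(tibble::tibble(variable = v, cohort = trend_cohort),
                         trend_tests(tsub[[v]], bins,
                                     tsub$collection_date))
      }))
      write_results(trend_tab, file.path(outdir, "trends.csv"),
                    provenance = prov)
    }
  }

  # cohort comparison (two largest cohorts)
  compare_tab <- NULL
  if (length(unique(complete$cohort)) >= 2) {
    top2 <- names(sort(table(complete$cohort), decreasing = TRUE))[1:2]
    csub <- complete[complete$cohort %in% top2, ]
    compare_tab <- compare_cohorts(csub[, value_cols], csub$cohort)
    write_results(compare_tab, file.path(outdir, "cohort_compare.csv"),
                  provenance = prov)
  }

  # batch effects and the correlation structure, per trend cohort
  batch_tab <- batch_effect_report(tsub[, value_cols], tsub$batch_id)
  write_results(batch_tab, file.path(outdir, "batch_report.csv"),
                provenance = prov)
  cm <- correlation_matrix(
    cbind(tsub[, value_cols], n_detected = tsub$n_detected)
  )
  cor_long <- tibble::as_tibble(as.data.frame(as.table(cm$rs),
                                              stringsAsFactors = FALSE))
  names(cor_long) <- c("var1", "var2", "spearman_rs")
  cor_long$p_value <- as.vector(cm$p)
  write_results(cor_long, file.path(outdir, "correlations.csv"),
                provenance = prov)

  invisible(list(summary = summary_tab, trends = trend_tab,
                 compare = compare_tab, batch = batch_tab,
                 correlations = cm))
}

#' Run the full pipeline end to end
#'
#' Convenience wrapper chaining all four stages under one seed and one output
#' root (subdirectories `sim/`, `validate/`, `quantify/`, `stats/`).
#'
#' @param outdir Root output directory.
#' @param seed Master seed.
#' @param panel A `neo_panel`.
#' @param config Optional `neo_sim_config`.
#' @param strict Propagated to the validate stage.
#' @return Invisibly, the stats-stage results.
#' @export
run_pipeline <- function(outdir, seed = 1L, panel = default_panel(),
                         config = NULL, strict = FALSE) {
  simdir <- file.path(outdir, "sim")
  run_simulate_stage(simdir, seed = seed, config = config, overwrite = TRUE)
  run_validate_stage(simdir, file.path(outdir, "validate"), panel = panel,
                     seed = seed, strict = strict)
  run_quantify_stage(simdir, file.path(outdir, "quantify"), panel = panel,
                     seed = seed)
  out <- run_stats_stage(file.path(outdir, "quantify"),
                         file.path(outdir, "stats"), seed = seed)
  invisible(out)
}
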