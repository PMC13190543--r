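#' Default per-analyte generating parameters
#'
#' Anchors the generator to the measured behaviour of the method: extraction
#' recoveries mostly 0.6-0.95, strong ionization suppression in pooled urine
#' (-0.669 to -0.36 as a fraction) and mild suppression in synthetic urine,
#' endogenous background in pooled-urine blanks for eight analytes (e.g. 0.30
#' ng/mL clothianidin), log-normal urinary concentration distributions, and
#' multiplicative temporal trends per 2-year bin for the analytes whose
#' population exposure is rising (THX, ACE-N-DES, FLU, SUL and its
#' metabolite).
#'
#' @param panel A `neo_panel`.
#' @return Tibble with one row per analyte: `analyte`, `recovery`,
#'   `me_pooled`, `me_synthetic` (fractions), `background` (ng/mL),
#'   `conc_median` (ng/mL), `conc_gsd`, `trend_per_bin`.
#' @export
default_sim_params <- function(panel = default_panel()) {
  p <- tibble::tribble(
    ~analyte,     ~recovery, ~me_pooled, ~conc_median, ~trend_per_bin,
    "ACE",        0.90,      -0.580,     0.002,        1.00,
    "CLO",        0.88,      -0.550,     0.070,        1.00,
    "IMI",        0.92,      -0.500,     0.040,        1.00,
    "THC",        0.85,      -0.480,     0.0005,       1.00,
    "THX",        0.90,      -0.520,     0.012,        1.15,
    "NIT",        0.80,      -0.669,     0.001,        1.00,
    "FLU",        0.86,      -0.450,     0.003,        1.25,
    "FLO",        0.75,      -0.420,     0.002,        1.00,
    "SUL",        0.84,      -0.470,     0.005,        1.30,
    "IMZ",        0.78,      -0.600,     0.010,        1.00,
    "ACE-N-DES",  0.88,      -0.384,     0.210,        1.12,
    "CLO-N-DES",  0.65,      -0.440,     0.020,        1.00,
    "CLO-U",      0.72,      -0.614,     0.001,        1.00,
    "5-OH-IMI",   0.86,      -0.490,     0.200,        1.00,
    "IMI-U",      0.59,      -0.360,     0.002,        1.00,
    "IMI-O",      0.88,      -0.460,     0.350,        1.00,
    "THC-A",      0.85,      -0.400,     0.0005,       1.00,
    "THX-N-DES",  0.83,      -0.530,     0.002,        1.00,
    "THX-U",      0.80,      -0.570,     0.005,        1.00,
    "NIT-N-DES",  0.62,      -0.630,     0.0003,       1.00,
    "SUL-X",      0.85,      -0.510,     0.003,        1.20
  )
  p <- p[match(panel$analytes$name, p$analyte), ]
  if (anyNA(p$analyte)) {
    # non-default panels fall back to mid-range behaviour
    p$analyte <- panel$analytes$name
    p$recovery[is.na(p$recovery)] <- 0.85
    p$me_pooled[is.na(p$me_pooled)] <- -0.50
    p$conc_median[is.na(p$conc_median)] <- 0.01
    p$trend_per_bin[is.na(p$trend_per_bin)] <- 1
  }
  p$me_synthetic <- 0.31 * p$me_pooled
  bg <- panel$analytes$blank_pooled
  p$background <- ifelse(is.na(bg), 0, bg)
  p$conc_gsd <- 3.5
  p[, c("analyte", "recovery", "me_pooled", "me_synthetic", "background",
        "conc_median", "conc_gsd", "trend_per_bin")]
}

#' Build a simulation configuration
#'
#' Collects every knob of the synthetic peak-area generator.  Scalar
#' overrides are recycled across the panel; named vectors override individual
#' analytes.  Matrix effects are fractions (must exceed -1: suppression
#' cannot remove more than the whole signal); noise CVs are fractions >= 0.
#'
#' @param seed Integer master seed; every generator derives its own
#'   deterministic substream from it.
#' @param panel A `neo_panel`.
#' @param recovery,me_pooled,me_synthetic,background,conc_median,conc_gsd,trend_per_bin
#'   Optional overrides of the per-analyte defaults (see
#'   [default_sim_params()]).
#' @param noise_cv Multiplicative instrument noise CV on analyte areas.
#' @param istd_cv Residual noise CV on ISTD areas (independent of the analyte
#'   channel, so ISTD correction is effective but imperfect).
#' @param calibration_levels Calibrator concentrations, ng/mL.
#' @param istd_conc Nominal in-vial ISTD concentration, ng/mL.
#' @param creatinine_median,creatinine_gsd Log-normal urinary creatinine
#'   distribution (mg/dL).
#' @param study_start,study_end Cohort collection window.
#' @param bin_width Width (years) of the temporal bins the trend applies to.
#' @return A `neo_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       panel = default_panel(),
                       recovery = NULL,
                       me_pooled = NULL,
                       me_synthetic = NULL,
                       background = NULL,
                       conc_median = NULL,
                       conc_gsd = NULL,
                       trend_per_bin = NULL,
                       noise_cv = 0.05,
                       istd_cv = 0.02,
                       calibration_levels = c(0.01, 0.025, 0.05, 0.1, 0.25,
                                              0.5, 1, 2.5, 5, 10, 25),
                       istd_conc = istd_nominal_conc(),
                       creatinine_median = 100,
                       creatinine_gsd = 1.6,
                       study_start = as.Date("2010-01-01"),
                       study_end = as.Date("2025-12-31"),
                       bin_width = 2) {
  params <- default_sim_params(panel)
  override <- function(tab, col, value) {
    if (is.null(value)) return(tab)
    if (!is.null(names(value))) {
      idx <- match(names(value), tab$analyte)
      if (anyNA(idx)) stop("override names not in panel: ",
                           paste(names(value)[is.na(idx)], collapse = ", "),
                           call. = FALSE)
      tab[[col]][idx] <- unname(value)
    } else {
      tab[[col]] <- rep_len(value, nrow(tab))
    }
    tab
  }
  params <- override(params, "recovery", recovery)
  params <- override(params, "me_pooled", me_pooled)
  params <- override(params, "me_synthetic",
                     if (is.null(me_synthetic) && !is.null(me_pooled)) {
                       0.31 * params$me_pooled
                     } else me_synthetic)
  params <- override(params, "background", background)
  params <- override(params, "conc_median", conc_median)
  params <- override(params, "conc_gsd", conc_gsd)
  params <- override(params, "trend_per_bin", trend_per_bin)

  if (noise_cv < 0 || istd_cv < 0) {
    stop("noise CVs must be non-negative", call. = FALSE)
  }
  if (any(params$me_pooled <= -1) || any(params$me_synthetic <= -1)) {
    stop("matrix effect must exceed -1 (suppression cannot exceed the ",
         "total signal)", call. = FALSE)
  }
  if (any(params$recovery <= 0 | params$recovery > 1)) {
    stop("recovery must be in (0, 1]", call. = FALSE)
  }
  if (any(params$background < 0)) {
    stop("endogenous background must be non-negative", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed),
    panel = panel,
    params = params,
    noise_cv = noise_cv,
    istd_cv = istd_cv,
    calibration_levels = calibration_levels,
    istd_conc = istd_conc,
    rf = 1e5,        # detector counts per ng/mL, analyte channel
    rf_istd = 8e4,   # detector counts per ng/mL, ISTD channel
    creatinine_median = creatinine_median,
    creatinine_gsd = creatinine_gsd,
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    bin_width = bin_width
  ), class = "neo_sim_config")
}

# deterministic substream seed (< 2^31) derived from the master seed
#' @keywords internal
stream_seed <- function(seed, k) {
  (abs(as.integer(seed)) %% 1000003L) * 1009L + as.integer(k)
}

# multiplicative log-normal noise with mean exactly 1 and the given CV
#' @keywords internal
lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' @keywords internal
istd_row <- function(config, n, recovery = 1, me = 0) {
  config$rf_istd * config$istd_conc * recovery * (1 + me) *
    lognoise(n, config$istd_cv)
}

#' Simulate a method-validation experiment
#'
#' Emits, per analyte and matrix (synthetic and pooled urine): matrix blanks,
#' pre-extraction fortified QC replicates at each QC level, pre- and
#' post-extraction matrix spikes at a fixed level for process-efficiency and
#' matrix-effect evaluation, and neat standards at the matching levels.
#'
#' Signal model for the analyte channel:
#' `area = rf * (background + spike) * recovery^(pre-extraction only) *
#' (1 + ME)^(in matrix) * lognormal-noise(noise_cv)`.
#' The ISTD is added before extraction, so for extracted samples its channel
#' carries the same recovery and matrix-effect factors as the analyte, with
#' its own independent residual noise: ISTD-ratio quantification is unbiased
#' by construction (isotope dilution corrects both extraction loss and
#' suppression) while recovery and suppression remain fully visible in the
#' raw analyte areas that PE and ME are computed from.  The residual ISTD
#' noise keeps the correction effective but imperfect.
#'
#' @param config A `neo_sim_config`.
#' @param n_replicates Replicates per level and matrix (>= 2).
#' @param qc_levels Fortification levels, ng/mL.
#' @param spike_level Matrix-spike level for PE/ME evaluation, ng/mL.
#' @return A list with `records` (peak-area tibble) and `truth` (the
#'   generating parameters actually used).
#' @export
simulate_validation_experiment <- function(config, n_replicates = 9,
                                           qc_levels = c(0.025, 0.25, 1.5, 4.5),
                                           spike_level = 1.5) {
  stopifnot(inherits(config, "neo_sim_config"))
  if (n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  if (any(qc_levels <= 0)) stop("qc_levels must be positive", call. = FALSE)
  set.seed(stream_seed(config$seed, 11L))

  rows <- list()
  add <- function(sample_id, analyte, role, matrix, area, istd_area,
                  nominal = NA_real_) {
    n <- length(area)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      sample_id = sample_id, analyte = analyte, role = role, matrix = matrix,
      batch_id = "VAL1", injection_index = 0L,
      area = area, istd_area = istd_area, nominal_conc = nominal
    )
  }

  for (i in seq_len(nrow(config$params))) {
    pr <- config$params[i, ]
    a <- pr$analyte
    for (mat in c("synthetic_urine", "pooled_urine")) {
      me <- if (mat == "pooled_urine") pr$me_pooled else pr$me_synthetic
      bg <- if (mat == "pooled_urine") pr$background else 0

      # matrix blanks (extracted; analyte content = endogenous background)
      add(sprintf("blank_%s_%d", mat, seq_len(n_replicates)), a, "blank", mat,
          config$rf * bg * pr$recovery * (1 + me) *
            lognoise(n_replicates, config$noise_cv),
          istd_row(config, n_replicates, pr$recovery, me))

      # fortified QC replicates (spiked before extraction)
      for (lv in qc_levels) {
        add(sprintf("qc_%s_%g_%d", mat, lv, seq_len(n_replicates)), a, "qc",
            mat,
            config$rf * (bg + lv) * pr$recovery * (1 + me) *
              lognoise(n_replicates, config$noise_cv),
            istd_row(config, n_replicates, pr$recovery, me), lv)
      }

      # PE/ME matrix spikes at the fixed spike level
      add(sprintf("pre_%s_%d", mat, seq_len(n_replicates)), a,
          "matrix_spike_pre", mat,
          config$rf * (bg + spike_level) * pr$recovery * (1 + me) *
            lognoise(n_replicates, config$noise_cv),
          istd_row(config, n_replicates, pr$recovery, me), spike_level)
      add(sprintf("post_%s_%d", mat, seq_len(n_replicates)), a,
          "matrix_spike_post", mat,
          config$rf * (bg * pr$recovery + spike_level) * (1 + me) *
            lognoise(n_replicates, config$noise_cv),
          istd_row(config, n_replicates, 1, me), spike_level)
    }

    # neat standards in solvent at every level used above
    for (lv in sort(unique(c(qc_levels, spike_level)))) {
      add(sprintf("neat_%g_%d", lv, seq_len(n_replicates)), a,
          "neat_standard", "solvent",
          config$rf * lv * lognoise(n_replicates, config$noise_cv),
          istd_row(config, n_replicates), lv)
    }
  }
  records <- dplyr::bind_rows(rows)
  records$injection_index <- seq_len(nrow(records))
  list(records = records, truth = config$params)
}

#' Simulate a calibration series
#'
#' Calibrant records in solvent at the configured levels (default 0.01-25
#' ng/mL) with the ISTD at its nominal 5 ng/mL equivalent; multiplicative
#' noise is applied independently to both channels.
#'
#' @param config A `neo_sim_config`.
#' @param n_replicates Injections per level.
#' @return Peak-area tibble of `calibrant` records.
#' @export
simulate_calibration_series <- function(config, n_replicates = 1) {
  stopifnot(inherits(config, "neo_sim_config"))
  levels <- config$calibration_levels
  if (any(levels <= 0)) stop("calibration levels must be positive",
                             call. = FALSE)
  if (length(levels) < 5) stop("need at least 5 calibration levels",
                               call. = FALSE)
  set.seed(stream_seed(config$seed, 12L))
  rows <- list()
  for (a in config$params$analyte) {
    for (lv in levels) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sprintf("cal_%g_%d", lv, seq_len(n_replicates)),
        analyte = a, role = "calibrant", matrix = "solvent",
        batch_id = "VAL1", injection_index = 0L,
        area = config$rf * lv * lognoise(n_replicates, config$noise_cv),
        istd_area = istd_row(config, n_replicates),
        nominal_conc = lv
      )
    }
  }
  records <- dplyr::bind_rows(rows)
  records$injection_index <- seq_len(nrow(records))
  records
}

#' Simulate a biomonitoring cohort dataset
#'
#' Draws per-sample, per-analyte urinary concentrations log-normally with
#' cohort- and time-dependent medians: each analyte's median is multiplied by
#' the cohort's exposure multiplier and by its configured trend factor once
#' per temporal bin elapsed since the study start.  Creatinine is drawn
#' log-normally per sample; batches are assigned box-by-box (consecutive
#' blocks), not randomized, matching how archived specimens are processed.
#' Measured concentrations carry multiplicative analytical noise; censoring
#' is left to the quantification stage so that detection-frequency structure
#' emerges from the configured limits rather than being hard-coded.
#'
#' @param config A `neo_sim_config`.
#' @param cohorts List of cohort specs: `list(name=, n=, start=, end=,
#'   multiplier=)`.  The default mirrors a two-cohort design of 246 pregnant
#'   women sampled 2010-2025 and 47 farmers sampled over one winter.
#' @param batch_size Samples per analytical batch.
#' @param measured_cv Analytical CV applied to measured concentrations
#'   (default: the ISTD-corrected ratio CV implied by the config).
#' @return A list with `samples`, `results` (measured ng/mL per sample and
#'   analyte) and `truth` (the noiseless generating concentrations).
#' @export
simulate_cohort <- function(config,
                            cohorts = list(
                              list(name = "pregnant_women", n = 246,
                                   start = "2010-01-01", end = "2025-12-31",
                                   multiplier = 1),
                              list(name = "farmers", n = 47,
                                   start = "2018-12-01", end = "2019-03-31",
                                   multiplier = 2.4)),
                            batch_size = 30,
                            measured_cv = NULL) {
  stopifnot(inherits(config, "neo_sim_config"))
  if (length(cohorts) == 0) stop("cohort list is empty", call. = FALSE)
  if (any(vapply(cohorts, function(co) co$n < 1, logical(1)))) {
    stop("cohort sizes must be >= 1", call. = FALSE)
  }
  if (is.null(measured_cv)) {
    measured_cv <- sqrt(config$noise_cv^2 + config$istd_cv^2)
  }
  set.seed(stream_seed(config$seed, 13L))

  start_year <- as.integer(format(config$study_start, "%Y"))
  samp_list <- list()
  res_list <- list()
  truth_list <- list()
  sidx <- 0L
  for (co in cohorts) {
    d0 <- as.Date(co$start); d1 <- as.Date(co$end)
    if (d1 < d0) stop("cohort date range is invalid", call. = FALSE)
    dates <- d0 + floor(stats::runif(co$n) * (as.numeric(d1 - d0) + 1))
    creat <- stats::rlnorm(co$n, log(config$creatinine_median),
                           log(config$creatinine_gsd))
    ids <- sprintf("%s_%03d", co$name, seq_len(co$n))
    samp_list[[co$name]] <- tibble::tibble(
      sample_id = ids, cohort = co$name, collection_date = dates,
      creatinine_mg_dl = creat, batch_id = NA_character_
    )
    bins <- floor((as.integer(format(dates, "%Y")) - start_year) /
                    config$bin_width)
    for (i in seq_len(nrow(config$params))) {
      pr <- config$params[i, ]
      med <- pr$conc_median * co$multiplier * pr$trend_per_bin^bins
      true_conc <- stats::rlnorm(co$n, log(med), log(pr$conc_gsd))
      measured <- true_conc * lognoise(co$n, measured_cv)
      res_list[[length(res_list) + 1L]] <- tibble::tibble(
        sample_id = ids, analyte = pr$analyte, raw_conc = measured
      )
      truth_list[[length(truth_list) + 1L]] <- tibble::tibble(
        sample_id = ids, analyte = pr$analyte, true_conc = true_conc
      )
    }
    sidx <- sidx + co$n
  }
  samples <- dplyr::bind_rows(samp_list)
  samples$batch_id <- sprintf("B%02d",
                              (seq_len(nrow(samples)) - 1L) %/% batch_size + 1L)
  list(samples = samples,
       results = dplyr::bind_rows(res_list),
       truth = dplyr::bind_rows(truth_list))
}

#' Simulate an ordered batch injection sequence
#'
#' Reproduces the standard run layout: three injections of a mid-range
#' calibrator to equilibrate, a solvent blank, a laboratory reagent blank,
#' the calibration series, a rinse, three pooled-urine matrix-spike QCs, a
#' water extract, then the unknowns with one re-analyzed calibrator
#' (`sample_id` prefix `midcal`) inserted after every ten unknowns.  An
#' optional per-injection sensitivity drift multiplies the analyte channel so
#' that downstream mid-run checks can detect instrument instability.
#'
#' @param config A `neo_sim_config`.
#' @param n_unknowns Number of unknown samples (must not exceed `max_unknowns`).
#' @param drift_per_injection Fractional analyte-channel drift per injection
#'   (e.g. 0.01 = +1% per injection).
#' @param midcal_level Concentration of the re-analyzed calibrator, ng/mL.
#' @param max_unknowns Per-run cap on unknowns.
#' @return Peak-area tibble in injection order.
#' @export
simulate_batch_sequence <- function(config, n_unknowns,
                                    drift_per_injection = 0,
                                    midcal_level = 1,
                                    max_unknowns = 150) {
  stopifnot(inherits(config, "neo_sim_config"))
  if (n_unknowns < 0 || n_unknowns > max_unknowns) {
    stop("n_unknowns must be between 0 and ", max_unknowns, call. = FALSE)
  }
  set.seed(stream_seed(config$seed, 14L))

  qc_pool_levels <- c(0.35, 1.75, 4.75)
  plan <- list()
  push <- function(sample_id, role, matrix, conc, nominal = NA_real_,
                   extracted = FALSE, spiked_post = FALSE) {
    plan[[length(plan) + 1L]] <<- list(sample_id = sample_id, role = role,
                                       matrix = matrix, conc = conc,
                                       nominal = nominal,
                                       extracted = extracted,
                                       spiked_post = spiked_post)
  }
  for (k in 1:3) push(sprintf("equil_%d", k), "calibrant", "solvent",
                      midcal_level, midcal_level)
  push("solvent_blank_1", "solvent_blank", "solvent", 0)
  push("lrb_1", "lrb", "solvent", 0)
  for (lv in config$calibration_levels) {
    push(sprintf("cal_%g", lv), "calibrant", "solvent", lv, lv)
  }
  push("rinse_1", "rinse", "solvent", 0)
  for (lv in qc_pool_levels) {
    push(sprintf("qcpool_%g", lv), "qc", "pooled_urine", lv, lv,
         extracted = TRUE)
  }
  push("water_1", "water", "solvent", 0)
  n_checks <- 0L
  if (n_unknowns > 0) {
    for (u in seq_len(n_unknowns)) {
      push(sprintf("unk_%03d", u), "unknown", "pooled_urine", NA_real_,
           extracted = TRUE)
      if (u %% 10 == 0) {
        n_checks <- n_checks + 1L
        push(sprintf("midcal_%02d", n_checks), "calibrant", "solvent",
             midcal_level, midcal_level)
      }
    }
  }

  rows <- list()
  for (j in seq_along(plan)) {
    pl <- plan[[j]]
    drift <- (1 + drift_per_injection)^(j - 1)
    for (i in seq_len(nrow(config$params))) {
      pr <- config$params[i, ]
      if (pl$extracted) {
        me <- pr$me_pooled
        conc <- if (is.na(pl$conc)) {
          stats::rlnorm(1, log(pr$conc_median), log(pr$conc_gsd))
        } else {
          pr$background + pl$conc
        }
        area <- config$rf * conc * pr$recovery * (1 + me) *
          lognoise(1, config$noise_cv)
        istd <- istd_row(config, 1, pr$recovery, me)
      } else {
        area <- config$rf * pl$conc * lognoise(1, config$noise_cv)
        istd <- istd_row(config, 1)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = pl$sample_id, analyte = pr$analyte, role = pl$role,
        matrix = pl$matrix, batch_id = "RUN1", injection_index = j,
        area = area * drift, istd_area = istd,
        nominal_conc = pl$nominal
      )
    }
  }
  dplyr::bind_rows(rows)
}
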