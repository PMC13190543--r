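#' Process efficiency of an extraction method
#'
#' Process efficiency (PE) compares the mean peak area of matrix samples
#' fortified *before* extraction against the mean area of neat standards at
#' the same nominal concentration:
#'
#'   PE (%) = 100 * mean(A_pre-extraction) / mean(A_neat)
#'
#' PE combines extraction recovery and matrix (ionization) effects and is the
#' quantity optimized when comparing SPE cartridges and wash solvents.
#'
#' @param pre_spike_areas Peak areas of pre-extraction spikes.
#' @param neat_areas Peak areas of neat standards at the same level.
#' @return A list with `pe_percent` and `sd_percent` (replicate spread of the
#'   pre-extraction areas propagated onto the PE scale).
#' @export
process_efficiency <- function(pre_spike_areas, neat_areas) {
  stopifnot(length(pre_spike_areas) > 0, length(neat_areas) > 0)
  neat_mean <- mean(neat_areas)
  if (!is.finite(neat_mean) || neat_mean <= 0) {
    stop("neat-standard mean area must be positive", call. = FALSE)
  }
  pe <- 100 * mean(pre_spike_areas) / neat_mean
  sd_pe <- if (length(pre_spike_areas) > 1) {
    100 * stats::sd(pre_spike_areas) / neat_mean
  } else {
    NA_real_
  }
  list(pe_percent = pe, sd_percent = sd_pe)
}

#' Matrix effect from a post-extraction spike
#'
#' Matrix effect (ME) compares matrix extracts fortified *after* extraction
#' against neat standards:
#'
#'   ME (%) = (mean(A_post-extraction) / mean(A_neat) - 1) * 100
#'
#' Negative values indicate ionization suppression, positive values
#' enhancement.
#'
#' @param post_spike_areas Peak areas of post-extraction spikes.
#' @param neat_areas Peak areas of neat standards at the same level.
#' @return A list with `me_percent` and `sd_percent`.
#' @export
matrix_effect <- function(post_spike_areas, neat_areas) {
  stopifnot(length(post_spike_areas) > 0, length(neat_areas) > 0)
  neat_mean <- mean(neat_areas)
  if (!is.finite(neat_mean) || neat_mean <= 0) {
    stop("neat-standard mean area must be positive", call. = FALSE)
  }
  me <- (mean(post_spike_areas) / neat_mean - 1) * 100
  sd_me <- if (length(post_spike_areas) > 1) {
    100 * stats::sd(post_spike_areas) / neat_mean
  } else {
    NA_real_
  }
  list(me_percent = me, sd_percent = sd_me)
}

#' Apparent extraction recovery from PE and ME
#'
#' Separates extraction loss from ionization suppression via the
#' post-extraction spike framework: RE = PE / (1 + ME), with ME expressed as
#' a fraction.  A PE of 38% with ME of -58% therefore implies roughly 90%
#' recovery: the low process efficiency is driven by ion suppression rather
#' than incomplete extraction.
#'
#' @param pe_percent Process efficiency, percent.
#' @param me_percent Matrix effect, percent (must exceed -100).
#' @return Apparent recovery, percent.
#' @export
apparent_recovery <- function(pe_percent, me_percent) {
  if (any(me_percent <= -100)) {
    stop("matrix effect of -100% or below leaves recovery undefined",
         call. = FALSE)
  }
  pe_percent / (1 + me_percent / 100)
}

#' Blank-corrected recovery
#'
#' For QC material prepared in a matrix with endogenous analyte, recovery is
#' corrected for the concentration already present before fortification:
#'
#'   recovery (%) = 100 * (final - initial) / spiked
#'
#' @param final_conc Measured concentration after fortification (ng/mL).
#' @param initial_conc Endogenous (blank) concentration (ng/mL), >= 0.
#' @param spiked_conc Fortification level (ng/mL), > 0.
#' @return Recovery, percent (signed; may exceed 100).
#' @export
blank_corrected_recovery <- function(final_conc, initial_conc, spiked_conc) {
  if (any(spiked_conc <= 0)) {
    stop("spiked concentration must be positive", call. = FALSE)
  }
  if (any(initial_conc < 0)) {
    stop("initial (blank) concentration cannot be negative", call. = FALSE)
  }
  100 * (final_conc - initial_conc) / spiked_conc
}

#' Detection and quantification limits from low-level replicates
#'
#' The limit of detection is 3 sigma and the limit of quantification 10
#' sigma, where sigma is the standard deviation of the measured
#' concentrations of low-level fortified QC replicates with all injections
#' pooled.  Full-precision values are returned; `reported_lod`/`reported_loq`
#' carry the two-significant-figure rendering used in reports.
#'
#' @param replicate_concs Measured concentrations (ng/mL) of the low-level QC
#'   replicates (>= 3 values), or `NULL` when `sigma` is given directly.
#' @param sigma Standard deviation of the method response (ng/mL).
#' @return A list with `sigma`, `lod`, `loq`, `reported_lod`, `reported_loq`.
#' @export
estimate_lod_loq <- function(replicate_concs = NULL, sigma = NULL) {
  if (is.null(sigma)) {
    if (is.null(replicate_concs) || length(replicate_concs) < 3) {
      stop("need at least 3 replicate concentrations (or sigma directly)",
           call. = FALSE)
    }
    sigma <- stats::sd(replicate_concs)
  }
  if (!is.finite(sigma) || sigma <= 0) {
    stop("sigma must be positive; zero replicate variance indicates a ",
         "degenerate experiment", call. = FALSE)
  }
  lod <- 3 * sigma
  loq <- 10 * sigma
  list(sigma = sigma, lod = lod, loq = loq,
       reported_lod = format_two_sig(lod),
       reported_loq = format_two_sig(loq))
}

#' Choose the matrix used for each analyte's detection-limit estimate
#'
#' Detection limits are normally estimated from low-level fortified pooled
#' urine.  For analytes with measurable endogenous concentrations in the
#' pooled-urine blank, the background inflates the low-level variance, so
#' background-free synthetic urine is used instead; limits from synthetic
#' urine are tagged method detection limits, those from pooled urine
#' practical reporting limits.
#'
#' @param blank_levels Tibble with columns `analyte` and `blank_pooled`
#'   (mean blank concentration, ng/mL; `NA` = not detected).
#' @param qcl_level Low-level fortification concentration, ng/mL.
#' @param threshold Blank level above which the pooled matrix is considered
#'   interfering.  The default, half the low-level fortification, routes
#'   every analyte whose endogenous background is comparable to the spike to
#'   synthetic urine while ignoring blank estimates at back-calculation noise
#'   level.
#' @return Tibble with `analyte`, `sigma_matrix` (`synthetic_urine` /
#'   `pooled_urine`) and `limit_kind` (`method_detection_limit` /
#'   `practical_reporting_limit`).
#' @export
select_lod_matrix <- function(blank_levels, qcl_level = 0.025,
                              threshold = qcl_level / 2) {
  if (is.null(blank_levels) || !all(c("analyte", "blank_pooled") %in%
                                      names(blank_levels))) {
    stop("blank_levels must have columns 'analyte' and 'blank_pooled'",
         call. = FALSE)
  }
  interfering <- !is.na(blank_levels$blank_pooled) &
    blank_levels$blank_pooled > threshold
  tibble::tibble(
    analyte      = blank_levels$analyte,
    sigma_matrix = ifelse(interfering, "synthetic_urine", "pooled_urine"),
    limit_kind   = ifelse(interfering, "method_detection_limit",
                          "practical_reporting_limit")
  )
}

#' Accuracy and precision of a QC level
#'
#' Accuracy is the mean measured concentration expressed as a percentage of
#' the spiking level; in matrices with endogenous background the
#' blank-corrected form `100 * (mean - blank) / nominal` is used.  Precision
#' is the relative standard deviation (RSD) of the measured concentrations.
#' A level passes when accuracy is within 70-130% and RSD is below 20%.
#'
#' @param measured_concs Measured concentrations at one QC level (>= 2).
#' @param nominal Spiking level, ng/mL (> 0).
#' @param blank_mean Endogenous blank concentration to subtract (default 0,
#'   the background-free synthetic-urine convention).
#' @param accuracy_band Length-2 acceptance band in percent.
#' @param rsd_limit Maximum acceptable RSD, percent.
#' @return A list with `accuracy_percent`, `sd`, `rsd_percent`, `pass`.
#' @export
evaluate_qc <- function(measured_concs, nominal, blank_mean = 0,
                        accuracy_band = c(70, 130), rsd_limit = 20) {
  if (length(measured_concs) < 2) {
    stop("need at least 2 replicates to evaluate a QC level", call. = FALSE)
  }
  if (!is.finite(nominal) || nominal <= 0) {
    stop("nominal QC level must be positive", call. = FALSE)
  }
  m <- mean(measured_concs)
  s <- stats::sd(measured_concs)
  accuracy <- 100 * (m - blank_mean) / nominal
  rsd <- if (m > 0) 100 * s / m else NA_real_
  pass <- is.finite(accuracy) && accuracy >= accuracy_band[1] &&
    accuracy <= accuracy_band[2] && is.finite(rsd) && rsd < rsd_limit
  list(accuracy_percent = accuracy, sd = s, rsd_percent = rsd, pass = pass)
}

#' Assemble a per-analyte validation summary table
#'
#' Computes, from a long peak-area table of a validation experiment, the full
#' per-analyte metric grid: process efficiency and matrix effect per matrix,
#' apparent recovery, pooled-urine blank level, 3-sigma/10-sigma LOD and LOQ
#' per matrix with matrix-selection tags, and accuracy/precision per QC level
#' and matrix.  Missing inputs (e.g. no post-extraction spikes for an
#' analyte) yield `NA` metrics for that analyte rather than dropping the row.
#'
#' @param records Peak-area tibble (see [read_peak_areas()]) containing neat
#'   standards, pre-/post-extraction spikes, matrix blanks and QC records.
#' @param panel A `neo_panel`.
#' @param curves Calibration curves (from [fit_calibration()], a tibble with
#'   one row per analyte) used to back-calculate concentrations.
#' @param qcl_level Low-level QC concentration used for LOD/LOQ estimation
#'   (ng/mL).
#' @return A list with `summary` (one row per panel analyte) and `qc` (long
#'   accuracy/precision grid per analyte, matrix and QC level).
#' @export
build_validation_table <- function(records, panel, curves,
                                   qcl_level = 0.025) {
  stopifnot(inherits(panel, "neo_panel"))
  analytes <- panel$analytes$name

  conc_of <- function(df) {
    if (nrow(df) == 0) return(numeric(0))
    vapply(seq_len(nrow(df)), function(i) {
      cv <- curves[curves$analyte == df$analyte[i], ]
      if (nrow(cv) == 0) return(NA_real_)
      back_calculate(cv, df$area[i] / df$istd_area[i])$conc
    }, numeric(1))
  }

  rows <- list()
  qc_rows <- list()
  for (a in analytes) {
    ra <- records[records$analyte == a, ]
    neat <- ra[ra$role == "neat_standard", ]
    blank_pool <- ra[ra$role == "blank" & ra$matrix == "pooled_urine", ]
    blank_mean <- if (nrow(blank_pool)) mean(conc_of(blank_pool)) else NA_real_

    pe_me_for <- function(mat) {
      pre  <- ra[ra$role == "matrix_spike_pre" & ra$matrix == mat, ]
      post <- ra[ra$role == "matrix_spike_post" & ra$matrix == mat, ]
      lv <- unique(stats::na.omit(c(pre$nominal_conc, post$nominal_conc)))
      lv <- if (length(lv)) max(lv) else NA_real_
      nt <- neat[!is.na(neat$nominal_conc) & neat$nominal_conc == lv, ]
      pe <- if (nrow(pre) && nrow(nt)) {
        process_efficiency(pre$area, nt$area)$pe_percent
      } else NA_real_
      me <- if (nrow(post) && nrow(nt)) {
        matrix_effect(post$area, nt$area)$me_percent
      } else NA_real_
      c(pe = pe, me = me)
    }
    pool <- pe_me_for("pooled_urine")
    synt <- pe_me_for("synthetic_urine")
    re <- if (is.finite(pool["pe"]) && is.finite(pool["me"]) &&
              pool["me"] > -100) {
      apparent_recovery(pool["pe"], pool["me"])
    } else NA_real_

    lod_for <- function(mat) {
      qcl <- ra[ra$role == "qc" & ra$matrix == mat &
                  !is.na(ra$nominal_conc) & ra$nominal_conc == qcl_level, ]
      if (nrow(qcl) < 3) return(c(lod = NA_real_, loq = NA_real_))
      est <- estimate_lod_loq(conc_of(qcl))
      c(lod = est$lod, loq = est$loq)
    }
    lim_syn <- lod_for("synthetic_urine")
    lim_pool <- lod_for("pooled_urine")

    tag <- select_lod_matrix(tibble::tibble(analyte = a,
                                            blank_pooled = if (is.finite(blank_mean) && blank_mean > 0) blank_mean else NA_real_),
                             qcl_level = qcl_level)

    rows[[a]] <- tibble::tibble(
      analyte = a,
      pe_pooled_percent = unname(pool["pe"]),
      me_pooled_percent = unname(pool["me"]),
      pe_synthetic_percent = unname(synt["pe"]),
      me_synthetic_percent = unname(synt["me"]),
      apparent_recovery_percent = unname(re),
      blank_pooled = blank_mean,
      synthetic_lod = unname(lim_syn["lod"]),
      synthetic_loq = unname(lim_syn["loq"]),
      pooled_lod = unname(lim_pool["lod"]),
      pooled_loq = unname(lim_pool["loq"]),
      sigma_matrix = tag$sigma_matrix,
      limit_kind = tag$limit_kind
    )

    qcs <- ra[ra$role == "qc" & !is.na(ra$nominal_conc), ]
    if (nrow(qcs)) {
      for (mat in unique(qcs$matrix)) {
        for (lv in sort(unique(qcs$nominal_conc[qcs$matrix == mat]))) {
          sub <- qcs[qcs$matrix == mat & qcs$nominal_conc == lv, ]
          if (nrow(sub) < 2) next
          bm <- if (mat == "pooled_urine" && is.finite(blank_mean)) {
            blank_mean
          } else 0
          ev <- evaluate_qc(conc_of(sub), lv, blank_mean = bm)
          qc_rows[[length(qc_rows) + 1L]] <- tibble::tibble(
            analyte = a, matrix = mat, level = lv, n = nrow(sub),
            accuracy_percent = ev$accuracy_percent, sd = ev$sd,
            rsd_percent = ev$rsd_percent, pass = ev$pass
          )
        }
      }
    }
  }
  list(summary = dplyr::bind_rows(rows), qc = dplyr::bind_rows(qc_rows))
}
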