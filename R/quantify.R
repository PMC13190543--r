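#' Censor a raw concentration against its detection limits
#'
#' Implements the substitution convention for left-censored urinary data:
#' values at or below the LOD are non-detects and are replaced by half the
#' LOD; detections between the LOD and LOQ are replaced by half the LOQ;
#' values at or above the LOQ are reported as measured.  Detection is
#' defined as strictly exceeding the LOD, so a value exactly equal to the LOD
#' counts as a non-detect; a value exactly equal to the LOQ counts as
#' quantified.
#'
#' @param raw_conc Raw back-calculated concentrations, ng/mL.
#' @param lod,loq Limits of detection/quantification, ng/mL (0 < lod < loq).
#' @return Tibble with columns `censoring` (`quantified`, `below_loq`,
#'   `non_detect`) and `reported_conc`.
#' @export
apply_censoring <- function(raw_conc, lod, loq) {
  if (any(!is.finite(lod)) || any(!is.finite(loq)) ||
      any(lod <= 0) || any(lod >= loq)) {
    stop("limits must satisfy 0 < lod < loq", call. = FALSE)
  }
  censoring <- ifelse(raw_conc <= lod, "non_detect",
                      ifelse(raw_conc < loq, "below_loq", "quantified"))
  reported <- ifelse(censoring == "non_detect", lod / 2,
                     ifelse(censoring == "below_loq", loq / 2, raw_conc))
  tibble::tibble(censoring = censoring, reported_conc = reported)
}

#' Creatinine-adjust a urinary concentration
#'
#' Normalizes a urinary concentration for dilution by dividing by urinary
#' creatinine, reported as micrograms of analyte per gram of creatinine:
#' ng/mL is ug/L and mg/dL is 10 mg/L, so ug/g = 100 * (ng/mL) / (mg/dL).
#' Missing or non-positive creatinine yields `NA` (the sample is excluded
#' from creatinine-adjusted outputs, never zero-filled).
#'
#' @param conc Concentration, ng/mL.
#' @param creatinine Urinary creatinine, mg/dL.
#' @return Adjusted concentration, ug/g creatinine (`NA` where creatinine is
#'   missing or non-positive).
#' @export
creatinine_adjust <- function(conc, creatinine) {
  ifelse(!is.na(creatinine) & creatinine > 0,
         100 * conc / creatinine, NA_real_)
}

#' Detection frequency of an analyte
#'
#' The proportion of samples whose concentration exceeds the limit of
#' detection (i.e. censoring status other than non-detect).
#'
#' @param censoring Character vector of censoring flags for one analyte.
#' @return List with `df_percent`, `n_detects`, `n`.
#' @export
detection_frequency <- function(censoring) {
  if (length(censoring) == 0) stop("no results supplied", call. = FALSE)
  n_det <- sum(censoring != "non_detect")
  list(df_percent = 100 * n_det / length(censoring),
       n_detects = n_det, n = length(censoring))
}

#' Aggregate exposure metrics for one sample
#'
#' Plain sums of member-analyte concentrations (substituted values included),
#' per the aggregate definitions in the panel.  Because clothianidin is a
#' thiamethoxam metabolite, the clothianidin aggregate members are a subset
#' of the thiamethoxam aggregate, so `sum_THX >= sum_CLO` for any
#' non-negative input.
#'
#' @param concs Named numeric vector of per-analyte concentrations for one
#'   sample (names are panel codes).
#' @param panel A `neo_panel`.
#' @return Named numeric vector, one element per aggregate.
#' @export
compute_aggregates <- function(concs, panel) {
  stopifnot(inherits(panel, "neo_panel"))
  vapply(panel$aggregates, function(members) {
    missing <- setdiff(members, names(concs))
    if (length(missing)) {
      stop("missing member analyte(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    sum(concs[members])
  }, numeric(1))
}

#' Number of analytes detected in one sample
#'
#' @param censoring Character vector of censoring flags covering the full
#'   panel for one sample.
#' @return Integer count of analytes with censoring other than non-detect.
#' @export
detects_per_sample <- function(censoring) {
  sum(censoring != "non_detect")
}

#' Quantify a cohort of samples
#'
#' Turns raw per-sample, per-analyte concentrations into reportable results:
#' censoring flags and half-LOD/half-LOQ substituted values using each
#' analyte's matrix-appropriate limits, creatinine-adjusted values (ug/g)
#' where creatinine is available, per-sample aggregate metrics on both
#' scales, and per-sample detection counts.
#'
#' @param results Tibble with `sample_id`, `analyte`, `raw_conc` (ng/mL).
#' @param samples Sample metadata tibble (see [read_samples()]).
#' @param panel A `neo_panel`.
#' @param limits Per-analyte limits tibble (`analyte`, `lod`, `loq`); default
#'   the panel's practical reporting limits.
#' @return A list with `results` (one row per sample x analyte: `raw_conc`,
#'   `censoring`, `reported_conc`, `adjusted_conc`), `aggregates` (one row
#'   per sample x aggregate with reported and adjusted sums) and `detects`
#'   (per-sample detection counts).
#' @export
quantify_samples <- function(results, samples, panel,
                             limits = panel_limits(panel, "pooled")) {
  stopifnot(inherits(panel, "neo_panel"))
  unknown <- setdiff(unique(results$analyte), panel$analytes$name)
  if (length(unknown)) {
    stop("analyte(s) not in panel: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  res <- dplyr::left_join(results, limits, by = "analyte")
  if (anyNA(res$lod) || anyNA(res$loq)) {
    stop("missing limits for analyte(s): ",
         paste(unique(res$analyte[is.na(res$lod) | is.na(res$loq)]),
               collapse = ", "), call. = FALSE)
  }
  cens <- apply_censoring(res$raw_conc, res$lod, res$loq)
  res$censoring <- cens$censoring
  res$reported_conc <- cens$reported_conc
  res <- dplyr::left_join(
    res,
    samples[, c("sample_id", "cohort", "collection_date", "creatinine_mg_dl",
                "batch_id")],
    by = "sample_id"
  )
  res$adjusted_conc <- creatinine_adjust(res$reported_conc,
                                         res$creatinine_mg_dl)

  per_sample <- split(res, res$sample_id)
  agg_rows <- lapply(per_sample, function(df) {
    rep_v <- stats::setNames(df$reported_conc, df$analyte)
    adj_v <- stats::setNames(df$adjusted_conc, df$analyte)
    agg_rep <- compute_aggregates(rep_v, panel)
    agg_adj <- if (anyNA(adj_v)) {
      stats::setNames(rep(NA_real_, length(agg_rep)), names(agg_rep))
    } else {
      compute_aggregates(adj_v, panel)
    }
    tibble::tibble(sample_id = df$sample_id[1],
                   aggregate = names(agg_rep),
                   reported_sum = unname(agg_rep),
                   adjusted_sum = unname(agg_adj))
  })
  det_rows <- lapply(per_sample, function(df) {
    tibble::tibble(sample_id = df$sample_id[1],
                   n_detected = detects_per_sample(df$censoring))
  })

  list(
    results = res[, c("sample_id", "analyte", "raw_conc", "censoring",
                      "reported_conc", "adjusted_conc", "cohort",
                      "collection_date", "creatinine_mg_dl", "batch_id")],
    aggregates = dplyr::bind_rows(agg_rows),
    detects = dplyr::bind_rows(det_rows)
  )
}
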