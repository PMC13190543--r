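#' Fit an internal-standard-normalized calibration curve
#'
#' Fits the response ratio (analyte area / ISTD area) against nominal
#' concentration by weighted least squares.  Isotope-dilution quantification
#' over several decades of concentration (here 0.01-25 ng/mL) practically
#' requires inverse weighting so that low calibrators are not swamped by the
#' absolute residuals of the high ones; `1/x` is therefore the default, with
#' `none` and `1/x^2` selectable.  A curve is flagged non-acceptable when its
#' weighted r-squared falls below 0.99 or its slope is not positive.
#'
#' @param calibrants Peak-area tibble of calibrant records for one analyte
#'   (requires >= 5 distinct levels, positive ISTD areas).
#' @param weighting `"1/x"` (default), `"none"`, or `"1/x^2"`.
#' @param r2_min Acceptance threshold for r-squared.
#' @return One-row tibble: `analyte`, `slope`, `intercept`, `r_squared`,
#'   `weighting`, `range_low`, `range_high`, `n_points`, `accepted`.
#' @export
fit_calibration <- function(calibrants, weighting = c("1/x", "none", "1/x^2"),
                            r2_min = 0.99) {
  weighting <- match.arg(weighting)
  analyte <- unique(calibrants$analyte)
  if (length(analyte) != 1) {
    stop("fit_calibration expects records for exactly one analyte",
         call. = FALSE)
  }
  conc <- calibrants$nominal_conc
  if (any(is.na(conc)) || any(conc <= 0)) {
    stop("calibrant levels must be positive and present", call. = FALSE)
  }
  if (length(unique(conc)) < 5) {
    stop("need at least 5 distinct calibration levels", call. = FALSE)
  }
  if (stats::var(conc) == 0) {
    stop("zero variance in calibration levels: singular fit", call. = FALSE)
  }
  if (any(calibrants$istd_area <= 0)) {
    stop("ISTD areas must be positive", call. = FALSE)
  }
  ratio <- calibrants$area / calibrants$istd_area
  w <- switch(weighting,
              "none"  = rep(1, length(conc)),
              "1/x"   = 1 / conc,
              "1/x^2" = 1 / conc^2)
  fit <- stats::lm(ratio ~ conc, weights = w)
  cf <- stats::coef(fit)
  r2 <- summary(fit)$r.squared
  slope <- unname(cf["conc"])
  tibble::tibble(
    analyte    = analyte,
    slope      = slope,
    intercept  = unname(cf["(Intercept)"]),
    r_squared  = r2,
    weighting  = weighting,
    range_low  = min(conc),
    range_high = max(conc),
    n_points   = length(conc),
    accepted   = is.finite(r2) && r2 >= r2_min && slope > 0
  )
}

#' Back-calculate a concentration from a calibration curve
#'
#' Inverts the linear curve: conc = (ratio - intercept) / slope.  Negative
#' estimates (ratio below the intercept) are floored at zero and flagged;
#' estimates above the calibrated range are flagged as extrapolated.
#'
#' @param curve One-row curve tibble from [fit_calibration()].
#' @param record Either a numeric response ratio, or a peak-area record row
#'   with `area` and `istd_area` columns.
#' @return A list with `conc` (ng/mL) and `flag` (`"ok"`,
#'   `"negative_estimate"`, or `"extrapolated_high"`).
#' @export
back_calculate <- function(curve, record) {
  if (nrow(curve) != 1) {
    stop("back_calculate expects a single calibration curve", call. = FALSE)
  }
  if (!is.finite(curve$slope) || curve$slope <= 0) {
    stop("invalid calibration curve: slope must be positive", call. = FALSE)
  }
  ratio <- if (is.numeric(record)) {
    record
  } else {
    if (any(record$istd_area <= 0)) {
      stop("record must have positive istd_area", call. = FALSE)
    }
    record$area / record$istd_area
  }
  conc <- (ratio - curve$intercept) / curve$slope
  flag <- ifelse(conc < 0, "negative_estimate",
                 ifelse(conc > curve$range_high, "extrapolated_high", "ok"))
  conc <- pmax(conc, 0)
  list(conc = conc, flag = flag)
}

#' Fit calibration curves for every analyte in a table
#'
#' @param calibrants Peak-area tibble with `role == "calibrant"` rows for one
#'   batch (other roles are ignored).
#' @inheritParams fit_calibration
#' @return Tibble with one row per analyte.
#' @export
fit_calibration_set <- function(calibrants, weighting = "1/x",
                                r2_min = 0.99) {
  cal <- calibrants[calibrants$role == "calibrant", ]
  if (nrow(cal) == 0) stop("no calibrant records supplied", call. = FALSE)
  dplyr::bind_rows(lapply(split(cal, cal$analyte), fit_calibration,
                          weighting = weighting, r2_min = r2_min))
}

#' Check mid-run calibrator stability
#'
#' An analytical run re-analyzes one calibration standard after every ten
#' unknowns to verify that instrument response stays stable.  Each re-check
#' is back-calculated through the batch's calibration curves and compared to
#' its nominal concentration; deviations beyond the tolerance are flagged
#' with their injection index.
#'
#' @param records Peak-area tibble of an injection sequence; mid-run
#'   re-checks are the `role == "calibrant"` rows whose `sample_id` starts
#'   with `"midcal"` (the convention used by [simulate_batch_sequence()]).
#' @param curves Curve tibble from [fit_calibration_set()].
#' @param tolerance Allowed relative deviation from nominal (default 0.20,
#'   matching the global precision acceptance bound).
#' @return Tibble with one row per re-check and analyte: `sample_id`,
#'   `injection_index`, `analyte`, `nominal_conc`, `measured_conc`,
#'   `deviation`, `pass`.  Zero rows when the sequence has no re-checks.
#' @export
check_midrun_calibrators <- function(records, curves, tolerance = 0.20) {
  chk <- records[records$role == "calibrant" &
                   grepl("^midcal", records$sample_id), ]
  if (nrow(chk) == 0) {
    return(tibble::tibble(sample_id = character(), injection_index = integer(),
                          analyte = character(), nominal_conc = double(),
                          measured_conc = double(), deviation = double(),
                          pass = logical()))
  }
  out <- lapply(seq_len(nrow(chk)), function(i) {
    cv <- curves[curves$analyte == chk$analyte[i], ]
    measured <- if (nrow(cv) == 1) {
      back_calculate(cv, chk[i, ])$conc
    } else NA_real_
    dev <- measured / chk$nominal_conc[i] - 1
    tibble::tibble(
      sample_id = chk$sample_id[i],
      injection_index = chk$injection_index[i],
      analyte = chk$analyte[i],
      nominal_conc = chk$nominal_conc[i],
      measured_conc = measured,
      deviation = dev,
      pass = is.finite(dev) && abs(dev) <= tolerance
    )
  })
  dplyr::bind_rows(out)
}
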