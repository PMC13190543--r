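#' @keywords internal
peak_area_roles <- c("calibrant", "qc", "blank", "lrb", "matrix_spike_pre",
                     "matrix_spike_post", "neat_standard", "unknown",
                     "solvent_blank", "rinse", "water")

#' @keywords internal
peak_area_cols <- c("sample_id", "analyte", "role", "matrix", "batch_id",
                    "injection_index", "area", "istd_area", "nominal_conc")

# roles that imply a known spike level and therefore require nominal_conc
#' @keywords internal
spiked_roles <- c("calibrant", "qc", "matrix_spike_pre", "matrix_spike_post",
                  "neat_standard")

#' Read a long-format peak-area table
#'
#' Reads one injection per row: the integrated analyte peak area and the
#' paired internal-standard area, with the role the injection plays in the
#' run (calibrant, QC, blank, pre-/post-extraction matrix spike, neat
#' standard, unknown, ...), the matrix it was prepared in, and its batch and
#' injection-sequence context.  Lines starting with `#` are treated as
#' provenance comments and skipped.
#'
#' @param path CSV path with columns `sample_id`, `analyte`, `role`,
#'   `matrix`, `batch_id`, `injection_index`, `area`, `istd_area`,
#'   `nominal_conc`.
#' @param panel Optional `neo_panel`; when supplied, analyte codes not in the
#'   panel are an error.
#' @return A tibble of typed records in file order.
#' @export
read_peak_areas <- function(path, panel = NULL) {
  raw <- readr::read_csv(path, comment = "#", col_types = readr::cols(
    sample_id       = readr::col_character(),
    analyte         = readr::col_character(),
    role            = readr::col_character(),
    matrix          = readr::col_character(),
    batch_id        = readr::col_character(),
    injection_index = readr::col_integer(),
    area            = readr::col_character(),
    istd_area       = readr::col_character(),
    nominal_conc    = readr::col_character()
  ), progress = FALSE)
  missing_cols <- setdiff(peak_area_cols, names(raw))
  if (length(missing_cols)) {
    stop("peak-area table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  num_field <- function(x, field, required = TRUE) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (required) bad <- union(bad, which(is.na(x)))
    if (length(bad)) {
      stop("non-numeric or missing '", field, "' in row(s): ",
           paste(utils::head(sort(bad), 10), collapse = ", "), call. = FALSE)
    }
    out
  }

  rec <- tibble::tibble(
    sample_id       = raw$sample_id,
    analyte         = raw$analyte,
    role            = raw$role,
    matrix          = raw$matrix,
    batch_id        = raw$batch_id,
    injection_index = raw$injection_index,
    area            = num_field(raw$area, "area"),
    istd_area       = num_field(raw$istd_area, "istd_area"),
    nominal_conc    = num_field(raw$nominal_conc, "nominal_conc",
                                required = FALSE)
  )

  bad_role <- setdiff(unique(rec$role), peak_area_roles)
  if (length(bad_role)) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  }
  if (any(rec$area < 0)) {
    stop("negative area in row(s): ",
         paste(utils::head(which(rec$area < 0), 10), collapse = ", "),
         call. = FALSE)
  }
  if (any(rec$istd_area <= 0)) {
    stop("istd_area must be positive; offending row(s): ",
         paste(utils::head(which(rec$istd_area <= 0), 10), collapse = ", "),
         call. = FALSE)
  }
  need_nominal <- rec$role %in% spiked_roles
  if (any(need_nominal & is.na(rec$nominal_conc))) {
    stop("nominal_conc required for spiked roles; missing in row(s): ",
         paste(utils::head(which(need_nominal & is.na(rec$nominal_conc)), 10),
               collapse = ", "), call. = FALSE)
  }
  if (!is.null(panel)) {
    unknown <- setdiff(unique(rec$analyte), panel$analytes$name)
    if (length(unknown)) {
      stop("analyte code(s) not in panel: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  rec
}

#' Read a sample-metadata table
#'
#' @param path CSV with columns `sample_id`, `cohort`, `collection_date`
#'   (ISO 8601), `creatinine_mg_dl`, `batch_id`.  Missing creatinine is kept
#'   as `NA`: such samples are excluded from creatinine-adjusted outputs but
#'   never zero-filled.
#' @param study_window Length-2 date vector; collection dates outside it are
#'   an error.  `NULL` skips the check.
#' @return A tibble in file order.
#' @export
read_samples <- function(path, study_window = NULL) {
  raw <- readr::read_csv(path, comment = "#", col_types = readr::cols(
    sample_id        = readr::col_character(),
    cohort           = readr::col_character(),
    collection_date  = readr::col_date(),
    creatinine_mg_dl = readr::col_double(),
    batch_id         = readr::col_character()
  ), progress = FALSE)
  if (any(!is.na(raw$creatinine_mg_dl) & raw$creatinine_mg_dl <= 0)) {
    stop("creatinine_mg_dl must be positive or missing", call. = FALSE)
  }
  if (!is.null(study_window)) {
    window <- as.Date(study_window)
    out_of_window <- raw$collection_date < window[1] |
      raw$collection_date > window[2]
    if (any(out_of_window, na.rm = TRUE)) {
      stop("collection_date outside study window in row(s): ",
           paste(utils::head(which(out_of_window), 10), collapse = ", "),
           call. = FALSE)
    }
  }
  raw
}

#' Format a value to two significant figures for reporting
#'
#' Detection and quantification limits are reported to two significant
#' figures; full precision is retained internally and only rendering is
#' affected.
#'
#' @param x Numeric vector.
#' @return Character vector (`NA` elements stay `NA`).
#' @export
format_two_sig <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  # round half away from zero in decimal at 2 significant digits, so that
  # e.g. 0.0455 reports as 0.046 regardless of binary representation, and
  # render with exactly two significant digits (trailing zeros kept)
  out[ok] <- vapply(x[ok], function(v) {
    if (v == 0) return("0.0")
    e <- floor(log10(abs(v)))
    scale <- 10^(e - 1)
    m <- signif(v / scale, 12)
    r <- sign(v) * floor(abs(m) + 0.5) * scale
    e_r <- floor(log10(abs(r)) + 1e-10)
    sprintf("%.*f", max(0L, 1L - e_r), r)
  }, character(1))
  out
}

#' Write a result table to CSV
#'
#' Writes with a stable column order and an optional provenance comment
#' header (`# key=value` lines) that [read_peak_areas()] and friends skip on
#' re-read.  Columns named `lod` or `loq` (or ending in `_lod`/`_loq`) are
#' rendered to two significant figures; all other numeric columns keep full
#' precision.
#'
#' @param table A non-empty data frame.
#' @param path Output path.
#' @param provenance Optional named character/list written as comment lines.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, provenance = NULL) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("refusing to write an empty result table", call. = FALSE)
  }
  out <- table
  limit_cols <- grep("(^|_)(lod|loq)$", names(out), value = TRUE)
  for (cl in limit_cols) {
    if (is.numeric(out[[cl]])) out[[cl]] <- format_two_sig(out[[cl]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", names(provenance), "=",
                      vapply(provenance, as.character, character(1))), con)
  }
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a peak-area or sample table verbatim (full precision)
#'
#' Companion to [write_results()] for pipeline interchange files where no
#' reporting-side rounding must be applied; round-trips through the matching
#' reader exactly.
#'
#' @inheritParams write_results
#' @export
write_table <- function(table, path, provenance = NULL) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("refusing to write an empty table", call. = FALSE)
  }
  header <- if (is.null(provenance)) {
    character(0)
  } else {
    paste0("# ", names(provenance), "=",
           vapply(provenance, as.character, character(1)))
  }
  writeLines(c(header, sub("\n$", "", readr::format_csv(table, na = ""))),
             path)
  invisible(path)
}
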