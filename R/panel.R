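#' Load and validate an analyte panel configuration
#'
#' A panel defines the analytes a targeted LC-MS/MS method quantifies: short
#' codes, parent/metabolite relations, the isotope-labeled internal standard
#' (ISTD) assigned to each analyte, per-matrix detection limits, endogenous
#' background measured in pooled-urine blanks, and the aggregate exposure
#' metrics (sums of parent plus metabolite concentrations) reported for it.
#'
#' The configuration is a JSON document with two top-level keys: `analytes`
#' (an array of objects with fields `name`, `kind`, `parent_of`, `istd`,
#' `lod_synthetic`, `loq_synthetic`, `lod_pooled`, `loq_pooled`,
#' `blank_pooled`, `cal_range_high`) and `aggregates` (a mapping from
#' aggregate name to member analyte codes).  Analyte codes are case-sensitive
#' keys used for joins throughout the pipeline.
#'
#' @param path Path to a panel JSON file.
#' @return An object of class `neo_panel`: a list with elements `name`,
#'   `analytes` (a tibble, one row per analyte in panel order) and
#'   `aggregates` (a named list of character vectors).
#' @seealso [default_panel()] for the panel shipped with the package.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) {
    stop("panel config not found: ", path, call. = FALSE)
  }
  cfg <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("panel config failed to parse: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(cfg$analytes) || length(cfg$analytes) == 0L) {
    stop("panel config has no analytes", call. = FALSE)
  }

  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  chr_or_na <- function(x) if (is.null(x)) NA_character_ else as.character(x)

  analytes <- dplyr::bind_rows(lapply(seq_along(cfg$analytes), function(i) {
    a <- cfg$analytes[[i]]
    for (f in c("name", "kind", "istd")) {
      if (is.null(a[[f]]) || !nzchar(a[[f]])) {
        stop("analyte entry ", i, " is missing required field '", f, "'",
             call. = FALSE)
      }
    }
    tibble::tibble(
      name           = as.character(a$name),
      kind           = as.character(a$kind),
      parent_of      = chr_or_na(a$parent_of),
      istd           = as.character(a$istd),
      panel_order    = i,
      lod_synthetic  = num_or_na(a$lod_synthetic),
      loq_synthetic  = num_or_na(a$loq_synthetic),
      lod_pooled     = num_or_na(a$lod_pooled),
      loq_pooled     = num_or_na(a$loq_pooled),
      blank_pooled   = num_or_na(a$blank_pooled),
      cal_range_high = num_or_na(a$cal_range_high)
    )
  }))

  if (anyDuplicated(analytes$name)) {
    dup <- unique(analytes$name[duplicated(analytes$name)])
    stop("duplicate analyte code(s) in panel: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (!all(analytes$kind %in% c("parent", "metabolite"))) {
    stop("analyte kind must be 'parent' or 'metabolite'", call. = FALSE)
  }
  bad_parent <- analytes$parent_of[!is.na(analytes$parent_of) &
                                     !(analytes$parent_of %in% analytes$name)]
  if (length(bad_parent)) {
    stop("parent_of refers to unknown analyte(s): ",
         paste(unique(bad_parent), collapse = ", "), call. = FALSE)
  }

  aggregates <- lapply(cfg$aggregates, function(m) as.character(unlist(m)))
  for (agg in names(aggregates)) {
    unknown <- setdiff(aggregates[[agg]], analytes$name)
    if (length(unknown)) {
      stop("aggregate '", agg, "' references unknown analyte(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  # structural constraint on the shipped aggregate design: total-clothianidin
  # members are a subset of total-thiamethoxam members (CLO is a THX metabolite)
  if (all(c("sum_CLO", "sum_THX") %in% names(aggregates)) &&
      !all(aggregates$sum_CLO %in% aggregates$sum_THX)) {
    stop("aggregate 'sum_CLO' must be a subset of 'sum_THX'", call. = FALSE)
  }
  if ("sum_NEO" %in% names(aggregates) &&
      !setequal(aggregates$sum_NEO, analytes$name)) {
    stop("aggregate 'sum_NEO' must contain every panel analyte", call. = FALSE)
  }

  structure(
    list(
      name       = if (is.null(cfg$name)) "panel" else as.character(cfg$name),
      analytes   = analytes,
      aggregates = aggregates
    ),
    class = "neo_panel"
  )
}

#' The default 21-analyte urinary neonicotinoid panel
#'
#' Ten parent neonicotinoids (ACE, CLO, IMI, THC, THX, NIT, FLU, FLO, SUL,
#' IMZ) and eleven metabolites (ACE-N-DES, CLO-N-DES, CLO-U, 5-OH-IMI, IMI-U,
#' IMI-O, THC-A, THX-N-DES, THX-U, NIT-N-DES, SUL-X), with five aggregate
#' exposure metrics: `sum_ACE`, `sum_CLO`, `sum_IMI`, `sum_THX` (which
#' includes the clothianidin group, clothianidin being a thiamethoxam
#' metabolite) and `sum_NEO` (all analytes).
#'
#' @return A `neo_panel` object.
#' @export
default_panel <- function() {
  load_panel(system.file("extdata", "neo21_panel.json", package = "neoquant",
                         mustWork = TRUE))
}

#' @export
print.neo_panel <- function(x, ...) {
  cat("<neo_panel> '", x$name, "': ", nrow(x$analytes), " analytes (",
      sum(x$analytes$kind == "parent"), " parents, ",
      sum(x$analytes$kind == "metabolite"), " metabolites), ",
      length(x$aggregates), " aggregates\n", sep = "")
  invisible(x)
}

#' Per-analyte reporting limits from a panel
#'
#' Returns the limit of detection (LOD) and quantification (LOQ) used for
#' censoring sample results.  The default set is the practical reporting
#' limits determined in pooled urine; `"synthetic"` selects the method
#' detection limits determined in background-free synthetic urine.
#'
#' @param panel A `neo_panel`.
#' @param source `"pooled"` (default) or `"synthetic"`.
#' @return A tibble with columns `analyte`, `lod`, `loq` (ng/mL).
#' @export
panel_limits <- function(panel, source = c("pooled", "synthetic")) {
  source <- match.arg(source)
  stopifnot(inherits(panel, "neo_panel"))
  if (source == "pooled") {
    tibble::tibble(analyte = panel$analytes$name,
                   lod = panel$analytes$lod_pooled,
                   loq = panel$analytes$loq_pooled)
  } else {
    tibble::tibble(analyte = panel$analytes$name,
                   lod = panel$analytes$lod_synthetic,
                   loq = panel$analytes$loq_synthetic)
  }
}

#' Nominal in-vial internal standard concentration
#'
#' Each calibrator or sample receives a fixed volume of ISTD working
#' solution; the nominal in-vial ISTD concentration is the spiked mass
#' divided by the final volume.  With the default 50 uL of a 100 ng/mL
#' working solution in a 1 mL calibrator this is 5 ng/mL.
#'
#' @param spike_volume_ul Spiked volume of ISTD working solution (uL).
#' @param working_conc_ng_ml Working-solution concentration (ng/mL).
#' @param final_volume_ml Final solution volume (mL).
#' @return Nominal ISTD concentration, ng/mL.
#' @export
istd_nominal_conc <- function(spike_volume_ul = 50,
                              working_conc_ng_ml = 100,
                              final_volume_ml = 1) {
  stopifnot(spike_volume_ul > 0, working_conc_ng_ml > 0, final_volume_ml > 0)
  (spike_volume_ul / 1000) * working_conc_ng_ml / final_volume_ml
}
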