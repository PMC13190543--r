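# Shared fixtures: tiny panels and noiseless configs built in code.

# a minimal syntactically valid panel with n analytes
tiny_panel_list <- function() {
  list(
    name = "tiny",
    analytes = list(
      list(name = "AAA", kind = "parent", parent_of = NULL, istd = "AAA-d3",
           lod_synthetic = 0.01, loq_synthetic = 0.033, lod_pooled = 0.02,
           loq_pooled = 0.066, blank_pooled = NULL, cal_range_high = 25),
      list(name = "AAA-M", kind = "metabolite", parent_of = "AAA",
           istd = "AAA-d3", lod_synthetic = 0.01, loq_synthetic = 0.033,
           lod_pooled = 0.02, loq_pooled = 0.066, blank_pooled = 0.1,
           cal_range_high = 25)
    ),
    aggregates = list(sum_AAA = list("AAA", "AAA-M"))
  )
}

write_panel_json <- function(panel_list, path = tempfile(fileext = ".json")) {
  jsonlite::write_json(panel_list, path, auto_unbox = TRUE, null = "null")
  path
}

# noiseless generator: every downstream estimator must equal its closed form
noiseless_config <- function(seed = 1, ...) {
  sim_config(seed = seed, noise_cv = 0, istd_cv = 0, ...)
}

# a well-formed peak-area tibble for io tests
example_records <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    analyte = c("ACE", "CLO", "IMI"),
    role = c("unknown", "calibrant", "qc"),
    matrix = c("pooled_urine", "solvent", "synthetic_urine"),
    batch_id = "B01",
    injection_index = 1:3,
    area = c(1000, 2000.5, 1500),
    istd_area = c(400000, 410000, 395000),
    nominal_conc = c(NA, 1, 0.25)
  )
}

# independent exhaustive-permutation oracle for the Kruskal-Wallis p value,
# written against the raw definition (chi-square-form statistic on mid-ranks
# with tie correction), separate from the package's implementation
oracle_kw_p <- function(values, groups) {
  groups <- as.integer(as.factor(groups))
  n <- length(values)
  stat <- function(g) {
    r <- rank(values)
    h <- 12 / (n * (n + 1)) *
      sum(tapply(r, g, sum)^2 / tapply(r, g, length)) - 3 * (n + 1)
    tie <- table(values)
    h / (1 - sum(tie^3 - tie) / (n^3 - n))
  }
  obs <- stat(groups)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  all_p <- vapply(perms(seq_len(n)), function(idx) stat(groups[idx]),
                  numeric(1))
  mean(all_p >= obs - 1e-12)
}
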