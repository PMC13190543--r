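test_that("process efficiency follows the pre-extraction/neat ratio", {
  expect_equal(process_efficiency(c(10, 10), c(10, 10))$pe_percent, 100)
  expect_equal(process_efficiency(c(3.7, 3.9), rep(10, 3))$pe_percent, 38)
  expect_error(process_efficiency(c(1, 2), c(0, 0)), "positive")
  expect_error(process_efficiency(numeric(0), 1))
})

test_that("matrix effect is signed per the suppression convention", {
  expect_equal(matrix_effect(c(5, 5), c(5, 5))$me_percent, 0)
  expect_equal(matrix_effect(0.42 * c(10, 10), c(10, 10))$me_percent, -58)
  expect_equal(matrix_effect(c(11, 11), c(10, 10))$me_percent, 10)
  expect_error(matrix_effect(c(1, 2), c(-1, 1)), "positive")
})

test_that("apparent recovery separates extraction loss from suppression", {
  expect_equal(apparent_recovery(38, -58), 38 / 0.42)
  expect_equal(round(apparent_recovery(38, -58)), 90)
  expect_equal(apparent_recovery(50, 0), 50)
  expect_equal(apparent_recovery(45, -50), 90)
  expect_error(apparent_recovery(38, -100), "undefined")
})

test_that("blank-corrected recovery subtracts the endogenous level", {
  expect_equal(blank_corrected_recovery(0.275, 0.025, 0.25), 100)
  expect_equal(blank_corrected_recovery(0.1, 0.1, 0.25), 0)
  expect_equal(blank_corrected_recovery(0.6, 0.1, 0.25), 200)
  expect_error(blank_corrected_recovery(1, 0, 0), "positive")
  expect_error(blank_corrected_recovery(1, -0.1, 0.25), "negative")
})

test_that("detection limits are 3 and 10 sigma with two-sig-fig reporting", {
  e <- estimate_lod_loq(sigma = 0.038)
  expect_equal(e$lod, 0.114)
  expect_equal(e$loq, 0.38)
  expect_equal(e$reported_lod, "0.11")
  expect_equal(e$reported_loq, "0.38")

  e2 <- estimate_lod_loq(sigma = 0.01)
  expect_equal(e2$reported_lod, "0.030")
  expect_equal(e2$reported_loq, "0.10")

  reps <- c(0.30, 0.36, 0.33, 0.31, 0.35)
  e3 <- estimate_lod_loq(reps)
  expect_equal(e3$sigma, sd(reps))
  expect_error(estimate_lod_loq(c(1, 2)), "at least 3")
  expect_error(estimate_lod_loq(rep(1, 5)), "degenerate")
})

test_that("LOQ/LOD is exactly 10/3 before rounding, for any sigma", {
  set.seed(1)
  for (sigma in exp(runif(50, log(1e-4), log(1)))) {
    e <- estimate_lod_loq(sigma = sigma)
    expect_equal(e$loq / e$lod, 10 / 3, tolerance = 1e-12)
  }
})

test_that("matrix selection reproduces the eight endogenous-background analytes", {
  p <- default_panel()
  tags <- select_lod_matrix(p$analytes[, c("name", "blank_pooled")] |>
                              stats::setNames(c("analyte", "blank_pooled")))
  synth <- tags$analyte[tags$sigma_matrix == "synthetic_urine"]
  expect_setequal(synth, c("CLO", "IMI", "THX", "ACE-N-DES", "CLO-N-DES",
                           "5-OH-IMI", "IMI-O", "THX-U"))
  expect_true(all(tags$limit_kind[tags$sigma_matrix == "pooled_urine"] ==
                    "practical_reporting_limit"))
  # all blanks non-detected: everything stays in pooled urine
  nd <- select_lod_matrix(tibble::tibble(analyte = c("A", "B"),
                                         blank_pooled = c(NA, NA)))
  expect_true(all(nd$sigma_matrix == "pooled_urine"))
  expect_error(select_lod_matrix(tibble::tibble(x = 1)), "must have columns")
})

test_that("QC evaluation applies the 70-130% / RSD<20% acceptance rules", {
  perfect <- evaluate_qc(rep(0.25, 9), 0.25)
  expect_equal(perfect$accuracy_percent, 100)
  expect_equal(perfect$rsd_percent, 0)
  expect_true(perfect$pass)

  low <- evaluate_qc(c(0.16, 0.165, 0.163), 0.25)
  expect_lt(low$accuracy_percent, 70)
  expect_false(low$pass)

  noisy <- evaluate_qc(c(0.1, 0.4, 0.25, 0.05, 0.45), 0.25)
  expect_gt(noisy$rsd_percent, 20)
  expect_false(noisy$pass)

  # pooled-urine convention: blank-corrected accuracy
  pooled <- evaluate_qc(rep(0.34, 5), 0.025, blank_mean = 0.30)
  expect_equal(pooled$accuracy_percent, 160)
  expect_false(pooled$pass)

  expect_error(evaluate_qc(c(1, 2), 0), "positive")
  expect_error(evaluate_qc(1, 1), "at least 2")
})

test_that("QC evaluation is scale invariant", {
  set.seed(7)
  x <- rlnorm(9, log(0.25), 0.08)
  base <- evaluate_qc(x, 0.25)
  for (c_mult in c(0.01, 3, 1000)) {
    scaled <- evaluate_qc(c_mult * x, c_mult * 0.25)
    expect_equal(scaled$accuracy_percent, base$accuracy_percent,
                 tolerance = 1e-12)
    expect_equal(scaled$rsd_percent, base$rsd_percent, tolerance = 1e-12)
  }
})

test_that("the validation table covers the panel and tolerates missing data", {
  cfg <- sim_config(seed = 12)
  v <- simulate_validation_experiment(cfg, n_replicates = 6)
  curves <- fit_calibration_set(simulate_calibration_series(cfg))
  # drop one analyte's post-extraction spikes: row stays, ME becomes NA
  rec <- v$records[!(v$records$analyte == "SUL" &
                       v$records$role == "matrix_spike_post"), ]
  vt <- build_validation_table(rec, default_panel(), curves)
  expect_equal(nrow(vt$summary), 21)
  sul <- vt$summary[vt$summary$analyte == "SUL", ]
  expect_true(is.na(sul$me_pooled_percent))
  expect_false(is.na(sul$pe_pooled_percent))
  expect_setequal(
    vt$summary$analyte[vt$summary$sigma_matrix == "synthetic_urine"],
    c("CLO", "IMI", "THX", "ACE-N-DES", "CLO-N-DES", "5-OH-IMI", "IMI-O",
      "THX-U"))
})
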