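test_that("the generator is deterministic in the seed", {
  a <- simulate_validation_experiment(sim_config(seed = 42), n_replicates = 3)
  b <- simulate_validation_experiment(sim_config(seed = 42), n_replicates = 3)
  expect_identical(a$records, b$records)
  c <- simulate_validation_experiment(sim_config(seed = 43), n_replicates = 3)
  expect_false(identical(a$records$area, c$records$area))

  x <- simulate_cohort(sim_config(seed = 5),
                       cohorts = list(list(name = "g", n = 10,
                                           start = "2015-01-01",
                                           end = "2016-01-01",
                                           multiplier = 1)))
  y <- simulate_cohort(sim_config(seed = 5),
                       cohorts = list(list(name = "g", n = 10,
                                           start = "2015-01-01",
                                           end = "2016-01-01",
                                           multiplier = 1)))
  expect_identical(x, y)
})

test_that("noiseless simulation reproduces every closed form exactly", {
  cfg <- noiseless_config(seed = 2, background = 0)
  v <- simulate_validation_experiment(cfg, n_replicates = 3)
  r <- v$records
  for (a in c("ACE", "IMI-U", "NIT")) {
    pr <- cfg$params[cfg$params$analyte == a, ]
    sub <- r[r$analyte == a, ]
    neat <- sub$area[sub$role == "neat_standard" & sub$nominal_conc == 1.5]
    pre <- sub$area[sub$role == "matrix_spike_pre" &
                      sub$matrix == "pooled_urine"]
    post <- sub$area[sub$role == "matrix_spike_post" &
                       sub$matrix == "pooled_urine"]
    pe <- process_efficiency(pre, neat)$pe_percent
    me <- matrix_effect(post, neat)$me_percent
    expect_equal(pe, 100 * pr$recovery * (1 + pr$me_pooled))
    expect_equal(me, 100 * pr$me_pooled)
    # the recovery identity inverts exactly
    expect_equal(apparent_recovery(pe, me), 100 * pr$recovery)
  }
  # worked identity: recovery 0.9 with ME -0.58 gives PE 37.8%
  cfg2 <- noiseless_config(seed = 2, background = 0, recovery = 0.9,
                           me_pooled = -0.58)
  v2 <- simulate_validation_experiment(cfg2, n_replicates = 2)
  sub <- v2$records[v2$records$analyte == "ACE", ]
  pe2 <- process_efficiency(
    sub$area[sub$role == "matrix_spike_pre" & sub$matrix == "pooled_urine"],
    sub$area[sub$role == "neat_standard" & sub$nominal_conc == 1.5]
  )$pe_percent
  expect_equal(pe2, 37.8)
})

test_that("noiseless calibration is an exact straight line", {
  cfg <- noiseless_config(seed = 3)
  cal <- simulate_calibration_series(cfg)
  curves <- suppressWarnings(fit_calibration_set(cal))
  expect_equal(curves$r_squared, rep(1, nrow(curves)), tolerance = 1e-12)
  expect_equal(curves$slope,
               rep(cfg$rf / (cfg$rf_istd * cfg$istd_conc), nrow(curves)),
               tolerance = 1e-12)
  expect_equal(curves$intercept, rep(0, nrow(curves)), tolerance = 1e-12)
  # back-calculation recovers every level exactly
  cv <- curves[curves$analyte == "THX", ]
  thx <- cal[cal$analyte == "THX", ]
  bc <- back_calculate(cv, thx)
  expect_equal(bc$conc, thx$nominal_conc, tolerance = 1e-10)
})

test_that("matrix-effect estimates recover configured values within 5 points", {
  # background-free material: the area-ratio ME estimator is only unbiased
  # when the matrix carries no endogenous analyte (see the biased case below)
  cfg <- sim_config(seed = 1, background = 0, noise_cv = 0.05,
                    istd_cv = 0.02)
  v <- simulate_validation_experiment(cfg, n_replicates = 9)
  r <- v$records
  for (i in seq_len(nrow(cfg$params))) {
    pr <- cfg$params[i, ]
    sub <- r[r$analyte == pr$analyte, ]
    neat <- sub$area[sub$role == "neat_standard" & sub$nominal_conc == 1.5]
    for (mat in c("pooled_urine", "synthetic_urine")) {
      post <- sub$area[sub$role == "matrix_spike_post" & sub$matrix == mat]
      est <- matrix_effect(post, neat)$me_percent
      truth <- 100 * (if (mat == "pooled_urine") pr$me_pooled
                      else pr$me_synthetic)
      expect_lt(abs(est - truth), 5)
    }
  }
})

test_that("endogenous background biases the raw area-ratio matrix effect", {
  # clothianidin-style case: 0.30 ng/mL blank against a 1.5 ng/mL spike
  # shifts the post-extraction/neat ratio upward by bg * recovery / spike
  cfg <- noiseless_config(seed = 1)
  v <- simulate_validation_experiment(cfg, n_replicates = 2)
  pr <- cfg$params[cfg$params$analyte == "CLO", ]
  sub <- v$records[v$records$analyte == "CLO", ]
  neat <- sub$area[sub$role == "neat_standard" & sub$nominal_conc == 1.5]
  post <- sub$area[sub$role == "matrix_spike_post" &
                     sub$matrix == "pooled_urine"]
  est <- matrix_effect(post, neat)$me_percent
  expected_bias <- 100 * (1 + pr$me_pooled) * pr$background * pr$recovery / 1.5
  expect_equal(est, 100 * pr$me_pooled + expected_bias, tolerance = 1e-10)
})

test_that("default ME parameters lie in the observed suppression ranges", {
  p <- default_sim_params()
  expect_true(all(p$me_pooled * 100 >= -66.9 & p$me_pooled * 100 <= -36.0))
  expect_true(all(p$me_synthetic * 100 > -21.4 & p$me_synthetic * 100 < -5.5))
  expect_true(all(p$background >= 0))
  # the eight endogenous-background analytes match the shipped panel blanks
  expect_equal(sum(p$background > 0), 8)
})

test_that("degenerate generator configurations are rejected", {
  expect_error(sim_config(noise_cv = -0.1), "non-negative")
  expect_error(sim_config(me_pooled = -1.2), "exceed -1")
  expect_error(sim_config(recovery = 1.4), "recovery")
  expect_error(sim_config(background = -1), "non-negative")
  expect_error(sim_config(calibration_levels = c(1, 2)) |>
                 simulate_calibration_series(), "at least 5")
  expect_error(simulate_calibration_series(
    sim_config(calibration_levels = c(-1, 1, 2, 3, 4))), "positive")
  expect_error(simulate_cohort(sim_config(), cohorts = list()), "empty")
  expect_error(simulate_validation_experiment(sim_config(),
                                              n_replicates = 1), ">= 2")
})

test_that("cohort generator covers sizes, dates and ground truth", {
  cfg <- sim_config(seed = 9)
  one <- simulate_cohort(cfg, cohorts = list(
    list(name = "solo", n = 1, start = "2020-01-01", end = "2020-12-31",
         multiplier = 1)))
  expect_equal(nrow(one$samples), 1)
  expect_equal(nrow(one$results), 21)
  expect_equal(nrow(one$truth), 21)

  two <- simulate_cohort(cfg)
  expect_equal(as.vector(table(two$samples$cohort)[c("pregnant_women",
                                                     "farmers")]),
               c(246, 47))
  expect_true(all(two$results$raw_conc > 0))
  # ground truth rides alongside but is a separate table
  expect_setequal(names(two$truth), c("sample_id", "analyte", "true_conc"))
  # farmers are sampled over a single winter
  fdates <- two$samples$collection_date[two$samples$cohort == "farmers"]
  expect_true(all(fdates >= as.Date("2018-12-01") &
                    fdates <= as.Date("2019-03-31")))
})

test_that("batch sequences follow the run layout", {
  cfg <- sim_config(seed = 4)
  seq20 <- simulate_batch_sequence(cfg, n_unknowns = 20)
  per_inj <- seq20[!duplicated(seq20$injection_index), ]
  # exactly floor(20/10) = 2 mid-run calibrator re-checks
  expect_equal(sum(grepl("^midcal", per_inj$sample_id)), 2)
  # prefix block: 3 equilibration injections, solvent blank, LRB,
  # 11 calibrants, rinse, 3 matrix-spike QCs, water extract
  expect_equal(per_inj$role[1:5],
               c("calibrant", "calibrant", "calibrant", "solvent_blank",
                 "lrb"))
  expect_equal(sum(per_inj$role == "qc"), 3)

  seq0 <- simulate_batch_sequence(cfg, n_unknowns = 0)
  expect_false(any(seq0$role == "unknown"))
  expect_false(any(grepl("^midcal", seq0$sample_id)))

  expect_error(simulate_batch_sequence(cfg, n_unknowns = 151), "between 0 and")
})
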