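test_that("exposure summaries report the Table-3 style statistics", {
  const <- summarize_exposure(rep(2.5, 10))
  expect_equal(const$mean, 2.5)
  expect_equal(const$median, 2.5)
  expect_equal(const$max, 2.5)
  expect_equal(const$sd, 0)
  expect_equal(const$ci_lower, const$ci_upper)

  single <- summarize_exposure(3.7)
  expect_equal(c(single$median, single$p75, single$p90, single$max),
               rep(3.7, 4))

  # mean of a log-normal column approaches its analytic moment
  set.seed(10)
  x <- rlnorm(4000, log(1), log(2))
  analytic <- exp(log(1) + log(2)^2 / 2)
  s <- summarize_exposure(x)
  expect_lt(abs(s$mean - analytic) / analytic, 0.05)
  expect_true(s$ci_lower < analytic && analytic < s$ci_upper)

  with_df <- summarize_exposure(c(1, 2, 3),
                                c("quantified", "below_loq", "non_detect"))
  expect_equal(with_df$df_percent, 100 * 2 / 3)
})

test_that("temporal bins are half-open calendar intervals", {
  expect_equal(assign_temporal_bins(as.Date("2011-06-15"), 2, 2010),
               "2010-2011")
  expect_equal(assign_temporal_bins(as.Date("2012-01-01"), 2, 2010),
               "2012-2013")
  expect_equal(assign_temporal_bins(as.Date("2024-07-01"), 5, 2010),
               "2020-2024")
  expect_equal(assign_temporal_bins(as.Date("2015-03-01"), 1, 2010), "2015")
  dates <- as.Date(c("2010-01-01", "2025-12-31", "2019-02-10"))
  expect_equal(assign_temporal_bins(dates, 2, 2010),
               c("2010-2011", "2024-2025", "2018-2019"))
  expect_error(assign_temporal_bins(as.Date("2009-12-31"), 2, 2010),
               "precedes")
})

test_that("small-sample Kruskal-Wallis equals the exhaustive permutation oracle", {
  v1 <- c(1, 2, 3, 4, 5, 6)
  g1 <- c("A", "A", "A", "B", "B", "B")
  kw1 <- kruskal_wallis(v1, g1)
  expect_equal(kw1$method, "exact")
  expect_equal(kw1$p_value, oracle_kw_p(v1, g1), tolerance = 1e-12)

  set.seed(3)
  v2 <- round(rnorm(7), 1)
  g2 <- c("A", "B", "C", "A", "B", "C", "A")
  kw2 <- kruskal_wallis(v2, g2)
  expect_equal(kw2$p_value, oracle_kw_p(v2, g2), tolerance = 1e-12)

  # with ties
  v3 <- c(1, 1, 2, 3, 3, 4, 2)
  g3 <- c("A", "A", "A", "B", "B", "B", "B")
  kw3 <- kruskal_wallis(v3, g3)
  expect_equal(kw3$p_value, oracle_kw_p(v3, g3), tolerance = 1e-12)
})

test_that("trend tests behave on monotone, tied, and invariant inputs", {
  dates <- as.Date("2012-01-01") + (0:19) * 200
  bins <- assign_temporal_bins(dates, 2, 2012)
  up <- seq_along(dates) * 1.0
  tt <- trend_tests(up, bins, dates)
  expect_equal(tt$spearman_rs, 1)
  expect_lt(tt$kw_p, 0.01)

  tied <- trend_tests(rep(1, 20), bins, dates)
  expect_true(tied$degenerate)
  expect_equal(tied$kw_p, 1)

  # rank statistics are invariant under strictly monotone transforms
  set.seed(5)
  x <- rlnorm(20)
  a <- trend_tests(x, bins, dates)
  b <- trend_tests(log(x), bins, dates)
  expect_equal(a$kw_p, b$kw_p, tolerance = 1e-12)
  expect_equal(a$spearman_rs, b$spearman_rs, tolerance = 1e-12)

  expect_error(trend_tests(x, rep("2012-2013", 20), dates), "2 non-empty")
})

test_that("correlation matrices are symmetric with unit diagonal", {
  set.seed(9)
  d <- tibble::tibble(a = rlnorm(40), b = rlnorm(40))
  d$dup <- d$a
  d$const <- 1
  cm <- correlation_matrix(d)
  expect_equal(cm$rs, t(cm$rs))
  expect_equal(unname(diag(cm$rs)), rep(1, 4))
  expect_equal(cm$rs["a", "dup"], 1)
  expect_lt(cm$p["a", "dup"], 1e-10)
  expect_true(is.na(cm$rs["a", "const"]))
  expect_equal(cm$constant_columns, "const")
  expect_error(correlation_matrix(d[1:2, ]), "at least 3")
})

test_that("correlated log-normal columns recover the configured rank correlation", {
  set.seed(11)
  n <- 400
  z1 <- rnorm(n)
  rho <- 0.7
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cm <- correlation_matrix(tibble::tibble(x = exp(z1), y = exp(z2)))
  # Spearman rho of a bivariate normal copula: (6/pi) * asin(rho/2)
  expected <- 6 / pi * asin(rho / 2)
  expect_lt(abs(cm$rs["x", "y"] - expected), 0.08)
})

test_that("cohort comparison is label-symmetric and detects separation", {
  set.seed(13)
  d <- tibble::tibble(conc = c(rlnorm(30, 0, 0.5), rlnorm(25, 3, 0.5)))
  g <- c(rep("g1", 30), rep("g2", 25))
  cc <- compare_cohorts(d, g)
  expect_lt(cc$p_value, 1e-8)
  cc_swapped <- compare_cohorts(d, ifelse(g == "g1", "g2", "g1"))
  expect_equal(cc$p_value, cc_swapped$p_value, tolerance = 1e-12)
  expect_equal(sort(c(cc$median_1, cc$median_2)),
               sort(c(cc_swapped$median_1, cc_swapped$median_2)))

  same <- compare_cohorts(tibble::tibble(conc = rep(2, 10)),
                          rep(c("a", "b"), 5))
  expect_equal(same$p_value, 1)

  expect_error(compare_cohorts(d, rep("one", 55)), "exactly 2")
  expect_error(compare_cohorts(d, c(rep("a", 54), "b")), ">= 2 samples")
})

test_that("batch-effect reports flag injected shifts and handle edge cases", {
  set.seed(17)
  n <- 60
  batch <- rep(sprintf("B%02d", 1:4), each = 15)
  # each batch sees an identical value set: exactly no batch association
  clean <- rep(exp(seq(-1, 1, length.out = 15)), 4)
  shifted <- clean * ifelse(batch == "B03", 8, 1)
  rep_tab <- batch_effect_report(tibble::tibble(clean = clean,
                                                shifted = shifted), batch)
  expect_false(rep_tab$flagged[rep_tab$variable == "clean"])
  expect_true(rep_tab$flagged[rep_tab$variable == "shifted"])

  single <- batch_effect_report(tibble::tibble(x = clean), rep("B1", n))
  expect_match(single$note, "not applicable")

  tiny <- batch_effect_report(tibble::tibble(x = rlnorm(5)),
                              c("B1", "B1", "B2", "B2", "B3"))
  expect_match(tiny$note, "size 1")
})

test_that("normality checks report both scales and degeneracies", {
  set.seed(19)
  skewed <- rlnorm(246, 0, 1.2)
  nc <- normality_check(skewed)
  expect_equal(nc$scale, c("raw", "log"))
  expect_lt(nc$p_value[nc$scale == "raw"], 0.05)
  expect_gt(nc$p_value[nc$scale == "log"], 0.05)

  with_zero <- normality_check(c(0, -1, skewed[1:20]))
  expect_equal(with_zero$n_excluded[with_zero$scale == "log"], 2)

  const <- normality_check(rep(1, 10))
  expect_true(all(const$degenerate))
  expect_error(normality_check(c(1, 2)), "3 <= n")
})
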