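#' Descriptive summary of one analyte's exposure distribution
#'
#' Computes the standard biomonitoring summary row on substituted,
#' creatinine-adjusted values: detection frequency, mean with a
#' normal-approximation 95% confidence interval, standard deviation, median,
#' 75th and 90th percentiles, and maximum.  Urinary exposure distributions
#' are typically right-skewed, so the medians and quantiles carry the
#' interpretive weight; the CI of the mean is reported for comparability and
#' is labeled as a normal approximation.
#'
#' @param values Numeric values (ug/g) for one analyte or aggregate.
#' @param censoring Optional censoring flags (same length) used for the
#'   detection frequency; `NULL` leaves DF fields `NA`.
#' @return One-row tibble: `df_percent`, `n_detects`, `n`, `mean`, `sd`,
#'   `ci_lower`, `ci_upper`, `median`, `p75`, `p90`, `max`.
#' @export
summarize_exposure <- function(values, censoring = NULL) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values to summarize", call. = FALSE)
  n <- length(values)
  m <- mean(values)
  s <- if (n > 1) stats::sd(values) else 0
  half <- stats::qnorm(0.975) * s / sqrt(n)
  df <- if (is.null(censoring)) {
    list(df_percent = NA_real_, n_detects = NA_integer_)
  } else {
    detection_frequency(censoring)
  }
  q <- stats::quantile(values, c(0.5, 0.75, 0.9), names = FALSE)
  tibble::tibble(
    df_percent = df$df_percent, n_detects = as.integer(df$n_detects), n = n,
    mean = m, sd = s, ci_lower = m - half, ci_upper = m + half,
    median = q[1], p75 = q[2], p90 = q[3], max = max(values)
  )
}

#' Assign collection dates to temporal bins
#'
#' Calendar-year bins of the given width anchored at `anchor_year`: a date in
#' year y falls in the bin starting at `anchor_year + width * floor((y -
#' anchor_year)/width)`.  Labels are `"2010-2011"` style for multi-year bins
#' and plain years for annual bins.
#'
#' @param dates Date vector.
#' @param width Bin width in years (1, 2, or 5 in routine use).
#' @param anchor_year First year of the first bin.
#' @return Character vector of bin labels (a factor level exists for every
#'   bin between the anchor and the last observed date).
#' @export
assign_temporal_bins <- function(dates, width = 2, anchor_year = 2010) {
  dates <- as.Date(dates)
  yr <- as.integer(format(dates, "%Y"))
  if (any(yr < anchor_year)) {
    stop("collection date precedes the anchor year", call. = FALSE)
  }
  lo <- anchor_year + width * ((yr - anchor_year) %/% width)
  if (width == 1) as.character(lo) else sprintf("%d-%d", lo, lo + width - 1)
}

# tie-corrected Kruskal-Wallis statistic (shared by the chi-square and the
# exact-permutation paths)
#' @keywords internal
kw_statistic <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  sums <- tapply(r, groups, sum)
  sizes <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(sums^2 / sizes) - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction <= 0) return(NA_real_)
  h / correction
}

#' Kruskal-Wallis test with an exact small-sample path
#'
#' Uses the tie-corrected chi-square approximation, switching automatically
#' to the exact permutation distribution (all distinct reassignments of the
#' observations to the group sizes) when the total sample size does not
#' exceed `exact_max_n`.  Degenerate input (all values tied) returns p = 1
#' with a flag rather than an error.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector (>= 2 non-empty groups).
#' @param exact_max_n Largest total n for which the exact distribution is
#'   enumerated.
#' @return List with `statistic`, `p_value`, `method` (`"exact"` or
#'   `"chi-square"`), `degenerate`.
#' @export
kruskal_wallis <- function(values, groups, exact_max_n = 12) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  if (length(unique(values)) == 1) {
    return(list(statistic = 0, p_value = 1, method = "degenerate",
                degenerate = TRUE))
  }
  n <- length(values)
  if (n <= exact_max_n) {
    obs <- kw_statistic(values, groups)
    sizes <- as.integer(table(groups))
    stats_all <- numeric(0)
    recurse <- function(remaining, assigned, level) {
      if (level == length(sizes)) {
        g <- integer(n)
        for (k in seq_along(assigned)) g[assigned[[k]]] <- k
        g[remaining] <- length(sizes)
        stats_all[length(stats_all) + 1L] <<- kw_statistic(values, g)
        return(invisible())
      }
      combos <- utils::combn(remaining, sizes[level], simplify = FALSE)
      for (cmb in combos) {
        recurse(setdiff(remaining, cmb), c(assigned, list(cmb)), level + 1L)
      }
    }
    recurse(seq_len(n), list(), 1L)
    p <- mean(stats_all >= obs - 1e-12)
    list(statistic = obs, p_value = p, method = "exact", degenerate = FALSE)
  } else {
    kt <- stats::kruskal.test(values, groups)
    list(statistic = unname(kt$statistic), p_value = kt$p.value,
         method = "chi-square", degenerate = FALSE)
  }
}

#' Temporal trend tests for one analyte
#'
#' Kruskal-Wallis across temporal bins (tie-corrected, exact by permutation
#' at small n) and Spearman rank correlation of the values against collection
#' date, both two-sided.
#'
#' @param values Numeric values (ug/g).
#' @param bins Temporal bin labels (see [assign_temporal_bins()]).
#' @param dates Collection dates.
#' @return One-row tibble: `kw_statistic`, `kw_p`, `spearman_rs`,
#'   `spearman_p`, `degenerate`.
#' @export
trend_tests <- function(values, bins, dates) {
  if (length(unique(bins)) < 2) {
    stop("need at least 2 non-empty temporal bins", call. = FALSE)
  }
  if (length(unique(values)) == 1) {
    return(tibble::tibble(kw_statistic = 0, kw_p = 1, spearman_rs = NA_real_,
                          spearman_p = 1, degenerate = TRUE))
  }
  kw <- kruskal_wallis(values, bins)
  sp <- suppressWarnings(
    stats::cor.test(values, as.numeric(as.Date(dates)), method = "spearman",
                    exact = FALSE)
  )
  tibble::tibble(
    kw_statistic = kw$statistic, kw_p = kw$p_value,
    spearman_rs = unname(sp$estimate), spearman_p = sp$p.value,
    degenerate = FALSE
  )
}

#' Pairwise Spearman correlation matrix
#'
#' Rank correlations and two-sided p values for every pair of columns
#' (analytes, optionally detection counts and aggregate burden), plus the
#' share of off-diagonal pairs reaching significance.  Constant columns have
#' undefined correlations; their pairs are `NA` and flagged.
#'
#' @param data Data frame or matrix of numeric columns (>= 3 rows).
#' @param alpha Significance threshold for the significant-pair share.
#' @return List with `rs` (symmetric, unit diagonal), `p`,
#'   `share_significant` (fraction of testable off-diagonal pairs with p <
#'   alpha), and `constant_columns`.
#' @export
correlation_matrix <- function(data, alpha = 0.05) {
  m <- as.data.frame(data)
  if (nrow(m) < 3) stop("need at least 3 samples", call. = FALSE)
  k <- ncol(m)
  nm <- names(m)
  const <- vapply(m, function(x) length(unique(x[!is.na(x)])) <= 1, logical(1))
  rs <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  pv <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(rs) <- 1
  diag(pv) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (const[i] || const[j]) next
      ct <- suppressWarnings(
        stats::cor.test(m[[i]], m[[j]], method = "spearman", exact = FALSE)
      )
      rs[i, j] <- rs[j, i] <- unname(ct$estimate)
      pv[i, j] <- pv[j, i] <- ct$p.value
    }
  }
  off_p <- pv[upper.tri(pv)]
  testable <- !is.na(off_p)
  list(
    rs = rs, p = pv,
    share_significant = if (any(testable)) {
      mean(off_p[testable] < alpha)
    } else NA_real_,
    constant_columns = nm[const]
  )
}

#' Compare two cohorts analyte by analyte
#'
#' Two-sided Wilcoxon rank-sum test per column with group medians reported
#' alongside.  Results are invariant to swapping the group labels.
#'
#' @param data Data frame of numeric columns (analytes and aggregates).
#' @param group Two-level grouping vector of length `nrow(data)`, each level
#'   with >= 2 samples.
#' @return Tibble: `variable`, `median_<group1>`, `median_<group2>`, `p_value`
#'   (group columns named `median_1`/`median_2` with a `groups` attribute
#'   giving the level order, sorted alphabetically).
#' @export
compare_cohorts <- function(data, group) {
  g <- as.factor(as.character(group))
  if (nlevels(g) != 2) stop("need exactly 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("each group needs >= 2 samples", call. = FALSE)
  lv <- levels(g)
  out <- lapply(names(data), function(nm) {
    x <- data[[nm]][g == lv[1]]
    y <- data[[nm]][g == lv[2]]
    p <- if (length(unique(c(x, y))) == 1) {
      1
    } else {
      suppressWarnings(stats::wilcox.test(x, y)$p.value)
    }
    tibble::tibble(variable = nm,
                   median_1 = stats::median(x, na.rm = TRUE),
                   median_2 = stats::median(y, na.rm = TRUE),
                   p_value = p)
  })
  res <- dplyr::bind_rows(out)
  attr(res, "groups") <- lv
  res
}

#' Batch-effect assessment
#'
#' For each analyte column: Kruskal-Wallis across analytical batches and
#' Spearman correlation against batch processing order.  Analytes with batch
#' p below `alpha` are flagged; batches of size one are included with a
#' small-sample note.
#'
#' @param data Data frame of numeric columns.
#' @param batch Batch labels, length `nrow(data)`; batch order is the sorted
#'   label order.
#' @param alpha Flagging threshold.
#' @return Tibble: `variable`, `kw_statistic`, `kw_p`, `spearman_rs`,
#'   `spearman_p`, `flagged`, `note`.  With a single batch, a one-row tibble
#'   noting the test is not applicable.
#' @export
batch_effect_report <- function(data, batch, alpha = 0.05) {
  b <- as.factor(as.character(batch))
  if (nlevels(b) < 2) {
    return(tibble::tibble(variable = NA_character_, kw_statistic = NA_real_,
                          kw_p = NA_real_, spearman_rs = NA_real_,
                          spearman_p = NA_real_, flagged = FALSE,
                          note = "single batch: batch-effect test not applicable"))
  }
  small <- any(table(b) < 2)
  order_idx <- as.numeric(b)
  out <- lapply(names(data), function(nm) {
    x <- data[[nm]]
    if (length(unique(x)) == 1) {
      return(tibble::tibble(variable = nm, kw_statistic = 0, kw_p = 1,
                            spearman_rs = NA_real_, spearman_p = 1,
                            flagged = FALSE, note = "constant values"))
    }
    kw <- kruskal_wallis(x, b, exact_max_n = 0)
    sp <- suppressWarnings(
      stats::cor.test(x, order_idx, method = "spearman", exact = FALSE)
    )
    tibble::tibble(
      variable = nm, kw_statistic = kw$statistic, kw_p = kw$p_value,
      spearman_rs = unname(sp$estimate), spearman_p = sp$p.value,
      flagged = is.finite(kw$p_value) && kw$p_value < alpha,
      note = if (small) "contains batch(es) of size 1" else ""
    )
  })
  dplyr::bind_rows(out)
}

#' Shapiro-Wilk normality check on raw and log scales
#'
#' @param values Numeric vector (3 <= n <= 5000 non-missing values).
#' @return Tibble: `scale`, `n_used`, `n_excluded` (non-positive values
#'   dropped from the log scale), `statistic`, `p_value`, `degenerate`.
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  one_scale <- function(x, label, excluded) {
    if (length(x) < 3 || length(unique(x)) == 1) {
      return(tibble::tibble(scale = label, n_used = length(x),
                            n_excluded = excluded, statistic = NA_real_,
                            p_value = NA_real_, degenerate = TRUE))
    }
    sw <- stats::shapiro.test(x)
    tibble::tibble(scale = label, n_used = length(x), n_excluded = excluded,
                   statistic = unname(sw$statistic), p_value = sw$p.value,
                   degenerate = FALSE)
  }
  pos <- values[values > 0]
  dplyr::bind_rows(
    one_scale(values, "raw", 0L),
    one_scale(log(pos), "log", n - length(pos))
  )
}
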