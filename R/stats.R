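# Group statistics of the study design: Welch's unpaired t (between groups),
# paired t (before/after valve replacement), simple least-squares regression
# and Bland-Altman style interobserver bias. All tests are two-sided and
# reported without multiple-testing correction, since the report lists raw
# per-comparison p-values.

#' Welch's unpaired t-test
#'
#' Two-sided unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom, computed from the closed-form definition.
#'
#' @param sample_a,sample_b Numeric vectors (>= 2 finite values each).
#' @return One-row tibble: `estimate` (mean a - mean b), `statistic`,
#'   `parameter` (df), `p.value`, `method`.
#' @export
welch_t <- function(sample_a, sample_b) {
  a <- sample_a[is.finite(sample_a)]
  b <- sample_b[is.finite(sample_b)]
  if (length(a) < 2L || length(b) < 2L) {
    abort("each sample needs >= 2 finite values", class = "svdecomp_stats_error")
  }
  va <- var(a)
  vb <- var(b)
  if (va + vb == 0) {
    abort("both samples are constant; the t statistic is undefined",
          class = "svdecomp_stats_error")
  }
  na <- length(a)
  nb <- length(b)
  se2 <- va / na + vb / nb
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  tibble(
    estimate = mean(a) - mean(b), statistic = t_stat, parameter = df,
    p.value = 2 * pt(-abs(t_stat), df), method = "Welch two-sample t-test"
  )
}

#' Paired t-test
#'
#' One-sample two-sided t-test on the within-pair differences
#' `after - before`.
#'
#' @param before,after Numeric vectors of equal length (>= 2 pairs).
#' @return One-row tibble: `estimate` (mean difference), `statistic`,
#'   `parameter` (df), `p.value`, `method`.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after)) {
    abort("before and after must have equal length", class = "svdecomp_stats_error")
  }
  keep <- is.finite(before) & is.finite(after)
  d <- (after - before)[keep]
  n <- length(d)
  if (n < 2L) {
    abort("need >= 2 complete pairs", class = "svdecomp_stats_error")
  }
  if (var(d) == 0) {
    abort("zero variance of the paired differences; the t statistic is undefined",
          class = "svdecomp_stats_error")
  }
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  tibble(
    estimate = mean(d), statistic = t_stat, parameter = n - 1,
    p.value = 2 * pt(-abs(t_stat), n - 1), method = "Paired t-test"
  )
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x` with coefficient of determination and
#' a two-sided t-test for the slope, computed from the closed-form normal
#' equations.
#'
#' @param x,y Numeric vectors (>= 3 complete pairs; `x` non-degenerate).
#' @return An `svd_linfit` object; `tidy()` gives per-term estimates,
#'   `glance()` the fit summary (`r.squared`, `p.value`, ...).
#' @export
linear_fit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    abort("need >= 3 complete (x, y) pairs", class = "svdecomp_stats_error")
  }
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) {
    abort("x is constant; the slope is undefined", class = "svdecomp_stats_error")
  }
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  se_slope <- sqrt(rss / (n - 2) / sxx)
  t_stat <- if (se_slope == 0) Inf else slope / se_slope
  p <- if (is.infinite(t_stat)) 0 else 2 * pt(-abs(t_stat), n - 2)
  structure(
    list(
      slope = slope, intercept = intercept, r.squared = r2,
      statistic = t_stat, p.value = p, df.residual = n - 2, n = n,
      se_slope = se_slope, x = x, y = y
    ),
    class = "svd_linfit"
  )
}

#' @export
print.svd_linfit <- function(x, ...) {
  cat(sprintf(
    "<svd_linfit> y = %.4g + %.4g x  (n = %d, R^2 = %.3f, slope p = %.3g)\n",
    x$intercept, x$slope, x$n, x$r.squared, x$p.value
  ))
  invisible(x)
}

#' @export
tidy.svd_linfit <- function(x, ...) {
  tibble(
    term = c("(Intercept)", "x"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$se_slope),
    statistic = c(NA_real_, x$statistic),
    p.value = c(NA_real_, x$p.value)
  )
}

#' @export
glance.svd_linfit <- function(x, ...) {
  tibble(
    r.squared = x$r.squared, statistic = x$statistic, p.value = x$p.value,
    df.residual = x$df.residual, nobs = x$n
  )
}

#' Interobserver bias
#'
#' Bland-Altman style paired percent differences between two observers'
#' measurements of the same quantities: `100 * (a - b) / mean(a, b)` per
#' pair, summarised as mean bias and SD.
#'
#' @param obs1,obs2 Numeric vectors of equal length (>= 2 pairs), positive
#'   reference values.
#' @return A list with `mean_bias_pct` and `sd_pct`.
#' @export
interobserver_bias <- function(obs1, obs2) {
  if (length(obs1) != length(obs2)) {
    abort("observer vectors must have equal length", class = "svdecomp_stats_error")
  }
  if (length(obs1) < 2L) {
    abort("need >= 2 measurement pairs", class = "svdecomp_stats_error")
  }
  m <- (obs1 + obs2) / 2
  if (any(!is.finite(m)) || any(m <= 0)) {
    abort("pair means must be positive", class = "svdecomp_stats_error")
  }
  d <- 100 * (obs1 - obs2) / m
  list(mean_bias_pct = mean(d), sd_pct = sd(d))
}

# Variables reported in the group table, in report order.
group_table_variables <- function(metrics) {
  canonical <- c(
    "pr_pct", "weight_kg", "lvedv_ml", "lvedvi_pct", "lvesv_ml", "lvesvi_pct",
    "lvsv_ml", "lvef_pct", "lv_longitudinal_pct", "lv_radial_pct",
    "lv_lateral_pct", "lv_septal_pct",
    "rvedv_ml", "rvedvi_pct", "rvesv_ml", "rvesvi_pct", "rvsv_ml", "rvef_pct",
    "rvef_corr_pct", "rv_longitudinal_pct", "rv_radial_pct",
    "rv_lateral_pct", "rv_septal_pct"
  )
  numeric_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1L))]
  numeric_cols <- setdiff(numeric_cols, c("thv_ml"))
  c(intersect(canonical, numeric_cols), setdiff(numeric_cols, canonical))
}

#' Group comparison table
#'
#' Builds the study-style summary report from a per-subject metrics table
#' ([subject_metrics()] rows): per group the mean, standard error of the mean
#' (SEM = SD / sqrt(n)) and n of complete cases per variable, plus Welch
#' p-values for each pair of groups and a significance flag at `alpha`.
#' Groups with a single contributing subject get an `NA` SEM and are omitted
#' from the p-value columns, with a warning.
#'
#' @param metrics Tibble with one row per subject (must contain `group`).
#' @param variables Variables to report; defaults to every numeric metric in
#'   report order.
#' @param groups Group levels in column order; missing groups are dropped
#'   with a warning.
#' @param alpha Significance level for the flag column (default 0.05).
#' @return An `svd_group_table`; `tidy()` returns the long form.
#' @export
build_group_table <- function(metrics, variables = NULL,
                              groups = c("control", "PR", "PPVR"),
                              alpha = 0.05) {
  metrics <- as_tibble(metrics)
  if (!"group" %in% names(metrics)) {
    abort("metrics must contain a 'group' column", class = "svdecomp_stats_error")
  }
  present <- intersect(groups, unique(metrics$group))
  if (length(present) < length(groups)) {
    warn(sprintf("group(s) %s absent from the metrics table; columns omitted",
                 paste(setdiff(groups, present), collapse = ", ")))
  }
  if (length(present) < 2L) {
    abort("need at least two groups to compare", class = "svdecomp_stats_error")
  }
  if (is.null(variables)) variables <- group_table_variables(metrics)

  pairs <- utils::combn(present, 2L, simplify = FALSE)
  rows <- lapply(variables, function(v) {
    row <- tibble(variable = v)
    vals <- lapply(present, function(g) {
      x <- metrics[[v]][metrics$group == g]
      x[is.finite(x)]
    })
    names(vals) <- present
    for (g in present) {
      x <- vals[[g]]
      n <- length(x)
      if (n == 1L) {
        warn(sprintf("variable %s, group %s: single subject; SEM undefined", v, g))
      }
      row[[paste0("mean_", g)]] <- if (n) mean(x) else NA_real_
      row[[paste0("sem_", g)]] <- if (n >= 2L) sd(x) / sqrt(n) else NA_real_
      row[[paste0("n_", g)]] <- n
    }
    for (pr in pairs) {
      cn <- paste0("p_", pr[1L], "_vs_", pr[2L])
      p <- tryCatch(
        welch_t(vals[[pr[1L]]], vals[[pr[2L]]])$p.value,
        svdecomp_stats_error = function(e) NA_real_
      )
      row[[cn]] <- p
      row[[paste0("sig_", pr[1L], "_vs_", pr[2L])]] <- !is.na(p) && p < alpha
    }
    row
  })
  structure(dplyr::bind_rows(rows),
            class = c("svd_group_table", "tbl_df", "tbl", "data.frame"),
            groups_present = present, alpha = alpha)
}

#' @export
tidy.svd_group_table <- function(x, ...) {
  present <- attr(x, "groups_present")
  long <- lapply(present, function(g) {
    tibble(
      variable = x$variable, group = g,
      mean = x[[paste0("mean_", g)]],
      sem = x[[paste0("sem_", g)]],
      n = x[[paste0("n_", g)]]
    )
  })
  dplyr::bind_rows(long)
}
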