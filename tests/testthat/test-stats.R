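# Statistical machinery: Welch and paired t, regression, interobserver bias,
# group report.

test_that("welch_t matches the reference implementation to 1e-10", {
  a <- c(1, 2, 3, 4)
  b <- c(2, 3, 4, 5)
  ours <- welch_t(a, b)
  ref <- t.test(a, b)
  expect_lt(abs(ours$statistic - unname(ref$statistic)), 1e-10)
  expect_lt(abs(ours$parameter - unname(ref$parameter)), 1e-10)
  expect_lt(abs(ours$p.value - ref$p.value), 1e-10)
  # a harder, unbalanced case
  set.seed(1)
  x <- rnorm(8, 73.6, 10.7)
  y <- rnorm(12, 60, 9)
  ours2 <- welch_t(x, y)
  ref2 <- t.test(x, y)
  expect_lt(abs(ours2$statistic - unname(ref2$statistic)), 1e-10)
  expect_lt(abs(ours2$p.value - ref2$p.value), 1e-10)
  # identical samples: t = 0, p = 1
  z <- c(1, 2, 3)
  same <- welch_t(z, z)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(welch_t(1, c(1, 2)), class = "svdecomp_stats_error")
  expect_error(welch_t(c(2, 2), c(2, 2)), class = "svdecomp_stats_error")
})

test_that("welch_t holds its nominal type-I error (simulated null)", {
  set.seed(20260929)
  reps <- 10000
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    rej[i] <- welch_t(rnorm(8), rnorm(12))$p.value < 0.05
  }
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("paired_t matches the reference implementation and rejects degenerate input", {
  before <- c(10, 11, 12, 13)
  after <- before + c(1, 1, 1, 2)
  ours <- paired_t(before, after)
  ref <- t.test(after, before, paired = TRUE)
  expect_lt(abs(ours$statistic - unname(ref$statistic)), 1e-10)
  expect_lt(abs(ours$p.value - ref$p.value), 1e-10)
  expect_equal(ours$parameter, 3)
  expect_error(paired_t(before, before), class = "svdecomp_stats_error")
  expect_error(paired_t(1:3, 1:4), class = "svdecomp_stats_error")
})

test_that("paired recovery at study scale is detected in >= 90% of seeded cohorts", {
  # PPVR subset: n = 6, prescribed longitudinal recovery of ~7 points with
  # a 3-point SD of the within-animal change
  set.seed(77)
  hits <- vapply(1:100, function(i) {
    before <- rnorm(6, 60, 9)
    after <- before + rnorm(6, 7, 3)
    paired_t(before, after)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("linear_fit matches lm and recovers a prescribed slope", {
  x <- c(1, 2, 3, 5, 8, 13)
  y <- c(2.1, 3.9, 6.2, 9.8, 16.1, 26.5)
  ours <- linear_fit(x, y)
  ref <- lm(y ~ x)
  expect_lt(abs(ours$slope - unname(coef(ref)[2])), 1e-10)
  expect_lt(abs(ours$intercept - unname(coef(ref)[1])), 1e-10)
  expect_lt(abs(ours$r.squared - summary(ref)$r.squared), 1e-10)
  expect_lt(abs(ours$p.value - summary(ref)$coefficients[2, 4]), 1e-10)
  # exact line: r2 = 1
  exact <- linear_fit(1:5, 2 * (1:5) + 1)
  expect_equal(exact$r.squared, 1)
  expect_error(linear_fit(rep(1, 5), rnorm(5)), class = "svdecomp_stats_error")
  expect_error(linear_fit(1:2, 1:2), class = "svdecomp_stats_error")
  # slope recovery: mean estimate within 10% of the prescribed coefficient
  set.seed(5)
  b <- 0.305
  slopes <- vapply(1:200, function(i) {
    x <- rnorm(8, 60, 9)
    y <- -10.3 + b * x + rnorm(8, 0, 0.7)
    linear_fit(x, y)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - b) / b, 0.1)
})

test_that("interobserver_bias uses pairwise-mean percent differences", {
  same <- interobserver_bias(c(100, 80, 120), c(100, 80, 120))
  expect_equal(same$mean_bias_pct, 0)
  expect_equal(same$sd_pct, 0)
  # hand-computed oracle: diffs 100*10/95 and -100*10/105
  ob <- interobserver_bias(c(100, 100), c(90, 110))
  d <- c(100 * 10 / 95, -100 * 10 / 105)
  expect_equal(ob$mean_bias_pct, mean(d), tolerance = 1e-12)
  expect_equal(ob$sd_pct, sd(d), tolerance = 1e-12)
  expect_equal(round(ob$sd_pct, 4), 14.1776)
  expect_error(interobserver_bias(c(1, -1), c(-1, 1)),
               class = "svdecomp_stats_error")
  expect_error(interobserver_bias(1:3, 1:2), class = "svdecomp_stats_error")
})

test_that("re-delineation scatter grows with contour noise", {
  # two 'observers' = two noise realisations of the same subject
  vols <- function(noise, seeds) {
    vapply(seeds, function(s) {
      suppressWarnings(
        ventricular_volumes(small_subject(seed = s, noise_sd_mm = noise)$study,
                            "LV")$edv_ml
      )
    }, numeric(1))
  }
  sds <- vapply(c(0.3, 1.5), function(noise) {
    o1 <- vols(noise, 1:4)
    o2 <- vols(noise, 5:8)
    interobserver_bias(o1, o2)$sd_pct
  }, numeric(1))
  expect_lt(sds[1], sds[2])
})

test_that("build_group_table reports mean/SEM/n and Welch p per pair", {
  set.seed(3)
  metrics <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:20),
    group = rep(c("control", "PR"), c(8, 12)),
    rv_longitudinal_pct = c(rnorm(8, 73.6, 10.7), rnorm(12, 60, 9)),
    rv_lateral_pct = c(rnorm(8, 34.7, 5.7), rnorm(12, 27, 6.2)),
    rv_septal_pct = c(rnorm(8, -2.8, 4.8), rnorm(12, 11, 5.5))
  )
  metrics$rv_radial_pct <- metrics$rv_lateral_pct + metrics$rv_septal_pct
  tab <- suppressWarnings(build_group_table(metrics))
  expect_s3_class(tab, "svd_group_table")
  r <- tab[tab$variable == "rv_longitudinal_pct", ]
  grp <- metrics$rv_longitudinal_pct[metrics$group == "control"]
  expect_equal(r$mean_control, mean(grp))
  expect_equal(r$sem_control, sd(grp) / sqrt(8)) # SEM = SD/sqrt(n)
  expect_identical(r$n_control, 8L)
  expect_equal(r$p_control_vs_PR,
               welch_t(grp, metrics$rv_longitudinal_pct[metrics$group == "PR"])$p.value)
  # report accounting: radial row equals lateral + septal rows, per group
  expect_equal(tab$mean_control[tab$variable == "rv_radial_pct"],
               tab$mean_control[tab$variable == "rv_lateral_pct"] +
                 tab$mean_control[tab$variable == "rv_septal_pct"])
  # long form
  td <- tidy(tab)
  expect_true(all(c("variable", "group", "mean", "sem", "n") %in% names(td)))
})

test_that("single-subject groups get NA SEM, a warning, and no p-value", {
  metrics <- tibble::tibble(
    group = c("control", "control", "PR"),
    lvsv_ml = c(60, 64, 52)
  )
  w <- testthat::capture_warnings(tab <- build_group_table(metrics))
  expect_true(any(grepl("single subject", w)))
  expect_true(is.na(tab$sem_PR))
  expect_true(is.na(tab$p_control_vs_PR))
})

test_that("a missing group drops its columns with a warning", {
  metrics <- tibble::tibble(group = rep(c("control", "PR"), each = 3),
                            lvsv_ml = c(60, 62, 64, 50, 52, 54))
  expect_warning(tab <- build_group_table(metrics), "PPVR")
  expect_false("mean_PPVR" %in% names(tab))
  expect_true("p_control_vs_PR" %in% names(tab))
})
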