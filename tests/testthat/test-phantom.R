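# Synthetic phantom: ground-truth construction, closure, determinism.

test_that("ground truth closes exactly: longitudinal + lateral + septal = SV", {
  for (seed in 1:5) {
    res <- small_subject(seed = seed)
    v <- res$truth$ventricles
    expect_lt(max(abs(v$longitudinal_ml + v$lateral_ml + v$septal_ml - v$sv_ml)),
              1e-9)
    expect_true(all(v$edv_ml >= v$esv_ml))
    expect_true(all(v$esv_ml > 0))
  }
})

test_that("ground-truth septal volumes of LV and RV are exact negatives", {
  res <- small_subject(seed = 3, septal_shift_mm = 1.2)
  v <- res$truth$ventricles
  expect_identical(v$septal_ml[v$ventricle == "LV"],
                   -v$septal_ml[v$ventricle == "RV"])
})

test_that("a pure-piston phantom has zero lateral and septal truth", {
  res <- small_subject(seed = 1, lateral_excursion_lv_mm = 0,
                       lateral_excursion_rv_mm = 0, septal_shift_mm = 0)
  v <- res$truth$ventricles
  expect_equal(v$lateral_ml, c(0, 0))
  expect_equal(v$septal_ml, c(0, 0))
  expect_equal(v$longitudinal_pct, c(100, 100))
})

test_that("a pure-concentric phantom (no AVP descent) has zero longitudinal truth", {
  res <- small_subject(seed = 1, avpd_lv_mm = 0, avpd_rv_mm = 0)
  v <- res$truth$ventricles
  expect_equal(v$longitudinal_ml, c(0, 0))
})

test_that("the emitted flow curve reproduces rf_target within 0.5 points", {
  for (rf in c(0, 0.1, 0.429, 0.7)) {
    res <- small_subject(seed = 2, rf_target = rf)
    ig <- integrate_flow(res$study$flow)
    rf_hat <- if (ig$forward_ml > 0) 100 * ig$retrograde_ml / ig$forward_ml else 0
    expect_lt(abs(rf_hat - 100 * rf), 0.5)
  }
})

test_that("increasing RV AVP descent strictly increases the true RV longitudinal fraction", {
  fracs <- vapply(c(4, 6, 8, 10), function(a) {
    res <- small_subject(seed = 1, avpd_rv_mm = a)
    truth_row(res$truth, "RV")$longitudinal_pct
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})

test_that("septal-only motion matches the analytic annular swept volume", {
  # septal arc of ~40 mm (radius 40/pi), radial shift 3 mm toward the LV,
  # 10 slices x 6 mm: exact annular volume s*arc*L - (pi/2)*s^2*L, of which
  # the textbook prism figure s*arc*L is the thin-band approximation
  r_sep <- 40 / pi
  wall <- 3
  p <- phantom_params(
    n_frames = 9, n_slices = 10, n_arc_vertices = 64,
    lv_radius_mm = r_sep - wall, wall_mm = wall, rv_wall_mm = 3,
    rv_crescent_outer_mm = 35, avpd_lv_mm = 6, avpd_rv_mm = 12,
    lateral_excursion_lv_mm = 0, lateral_excursion_rv_mm = 0,
    septal_shift_mm = 3, thv_ml = 200
  )
  res <- generate_subject(p, seed = 1)
  sep_lv <- truth_row(res$truth, "LV")$septal_ml
  L <- 60
  annular <- (3 * (pi * r_sep) - pi / 2 * 9) * L / 1000
  prism <- 3 * 40 * L / 1000
  expect_equal(sep_lv, annular, tolerance = 2e-3)   # polygonization only
  expect_equal(sep_lv, prism, tolerance = 0.15)     # thin-band approximation
  expect_equal(truth_row(res$truth, "RV")$septal_ml, -sep_lv)

  # rasterized-integration oracle: area between the two septal arc positions,
  # via Monte-Carlo winding-number sampling of ED/ES epicardial regions
  ed <- get_poly(res$study, 0, 5, "lv_epi")
  es <- get_poly(res$study, res$truth$es_frame, 5, "lv_epi")
  set.seed(99)
  bbox <- c(min(ed[, 1], es[, 1]), max(ed[, 1], es[, 1]),
            min(ed[, 2], es[, 2]), max(ed[, 2], es[, 2]))
  d_area <- mc_polygon_area_fast(ed, 4e5, bbox) - mc_polygon_area_fast(es, 4e5, bbox)
  expect_equal(d_area * L / 1000, annular, tolerance = 0.05)
})

test_that("cohort generation is deterministic and honours the group design", {
  spec_c <- group_spec("control", 3, small_params(),
                       sd = list(avpd_lv_mm = 1, lv_radius_mm = 1),
                       covariates = list(weight = list(mean = 55, sd = 5),
                                         pcwp = list(a = 10, b = 0, sd = 2)))
  spec_p <- group_spec("PR", 4, small_params(septal_shift_mm = -0.8,
                                             rf_target = 0.4),
                       sd = list(avpd_rv_mm = 1))
  c1 <- generate_cohort(list(spec_c, spec_p), seed = 42)
  c2 <- generate_cohort(list(spec_c, spec_p), seed = 42)
  expect_identical(length(c1), 7L)
  expect_equal(c1, c2)
  groups <- vapply(c1, function(s) s$study$group, character(1))
  expect_identical(as.integer(table(groups)[c("control", "PR")]), c(3L, 4L))
  expect_true(all(c("weight_kg", "pcwp_mmhg") %in%
                    names(c1$control_01$study$covariates)))
  # different seed, different draws
  c3 <- generate_cohort(list(spec_c, spec_p), seed = 43)
  expect_false(identical(c1$control_01$study$contours,
                         c3$control_01$study$contours))
})

test_that("zero between-subject SD yields identical ground truth across subjects", {
  spec <- group_spec("control", 3, small_params())
  cohort <- generate_cohort(spec, seed = 7)
  truths <- lapply(cohort, function(s) s$truth$ventricles)
  expect_equal(truths[[1]], truths[[2]])
  expect_equal(truths[[1]], truths[[3]])
})

test_that("geometrically impossible parameter sets raise parameter errors", {
  expect_error(phantom_params(rv_crescent_outer_mm = 20),
               class = "svdecomp_parameter_error") # inside the LV epicardium
  expect_error(phantom_params(rf_target = 1.2),
               class = "svdecomp_parameter_error")
  expect_error(phantom_params(n_frames = 2),
               class = "svdecomp_parameter_error")
  # descent beyond the stack is rejected at construction
  expect_error(small_params(avpd_lv_mm = 30), class = "svdecomp_parameter_error")
  # motion ejecting more than EDV is rejected at generation
  expect_error(generate_subject(small_params(avpd_lv_mm = 20), seed = 1),
               class = "svdecomp_parameter_error")
  # cohort errors name the offending subject
  spec <- group_spec("PR", 2, small_params(avpd_lv_mm = 20))
  expect_error(generate_cohort(spec, seed = 1), "PR_01",
               class = "svdecomp_parameter_error")
})

test_that("preset calibration reproduces its volumetric targets in the ground truth", {
  for (nm in c("control", "pr", "ppvr")) {
    p <- phantom_preset(nm)
    res <- generate_subject(p, seed = 1)
    v <- res$truth$ventricles
    y <- yaml::read_yaml(system.file("extdata", "presets", paste0(nm, ".yaml"),
                                     package = "svdecomp"))
    tg <- y$targets
    expect_equal(v$edv_ml[v$ventricle == "LV"], tg$edv_lv_ml, tolerance = 1e-6)
    expect_equal(v$sv_ml[v$ventricle == "LV"], tg$sv_lv_ml, tolerance = 1e-6)
    expect_equal(v$edv_ml[v$ventricle == "RV"], tg$edv_rv_ml, tolerance = 1e-6)
    expect_equal(v$sv_ml[v$ventricle == "RV"], tg$sv_rv_ml, tolerance = 1e-6)
    lv_pct <- unlist(tg$lv_pct)
    want <- 100 * lv_pct / sum(lv_pct)
    got <- unlist(v[v$ventricle == "LV",
                    c("longitudinal_pct", "lateral_pct", "septal_pct")])
    expect_equal(unname(got), want, tolerance = 1e-6)
    expect_equal(res$truth$rf_pct, 100 * tg$rf_target, tolerance = 1e-9)
  }
})
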