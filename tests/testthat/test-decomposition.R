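# Stroke-volume decomposition: AVP displacement, reference area, swept-wall
# volumes, accounting identities and phantom recovery.

test_that("avp_displacement averages landmark displacements ED to ES", {
  mk <- function(positions_es) {
    tidyr::expand_grid(landmark_id = sprintf("m%d", seq_along(positions_es)),
                       frame = 0:1) |>
      dplyr::mutate(ventricle = "RV", time_ms = frame * 30,
                    position_mm = ifelse(frame == 0, 0,
                                         positions_es[as.integer(sub("m", "", landmark_id))]))
  }
  expect_equal(avp_displacement(mk(rep(12, 7)), "RV", 0, 1), 12)
  expect_equal(avp_displacement(mk(c(10, 12, 14)), "RV", 0, 1), 12)
  expect_error(avp_displacement(mk(rep(12, 7)), "LV", 0, 1),
               class = "svdecomp_input_error") # no LV tracks
  expect_error(avp_displacement(mk(rep(12, 7)), "RV", 0, 5),
               class = "svdecomp_input_error") # missing frame
  # phantom: measured displacement equals the prescribed peak exactly
  res <- small_subject(seed = 1)
  expect_equal(avp_displacement(res$study, "LV", 0, res$truth$es_frame),
               8, tolerance = 1e-12)
})

test_that("longitudinal_reference_area is the mean of the three largest epicardial areas", {
  areas <- c(2000, 1900, 1800, 1500)
  s <- toy_study(list(sqrt(areas)))
  expect_equal(longitudinal_reference_area(s, "LV", 0), mean(c(2000, 1900, 1800)))
  s_eq <- toy_study(list(rep(sqrt(1700), 5)))
  expect_equal(longitudinal_reference_area(s_eq, "LV", 0), 1700)
  s_few <- toy_study(list(c(40, 42)))
  expect_error(longitudinal_reference_area(s_few, "LV", 0),
               class = "svdecomp_input_error")
  # cylinder phantom: all slices share pi*R^2 up to polygonization
  p <- phantom_params(n_frames = 5, n_slices = 4, lv_radius_mm = 17,
                      wall_mm = 8, avpd_lv_mm = 4, avpd_rv_mm = 4,
                      lateral_excursion_lv_mm = 1, lateral_excursion_rv_mm = 2,
                      septal_shift_mm = 0.2, n_arc_vertices = 64)
  res <- generate_subject(p, seed = 1)
  expect_equal(longitudinal_reference_area(res$study, "LV", 0), pi * 25^2,
               tolerance = 1e-3)
})

test_that("longitudinal_volume multiplies displacement by reference area", {
  expect_equal(longitudinal_volume(10, 1900), 19)
  expect_equal(longitudinal_volume(0, 1900), 0)
  expect_equal(longitudinal_volume(-3, 1000), -3)
  expect_error(longitudinal_volume(10, 0), class = "svdecomp_parameter_error")
})

test_that("swept_wall_volumes: identical frames sweep nothing; errors are classed", {
  res <- small_subject(seed = 1)
  sw <- swept_wall_volumes(res$study, "LV", 0, 0, resolution_mm = 0.5)
  expect_equal(sw$lateral_ml, 0)
  expect_equal(sw$septal_ml, 0)
  expect_error(swept_wall_volumes(res$study, "LV", 0, 4, resolution_mm = -1),
               class = "svdecomp_parameter_error")
  s <- res$study
  s$contours <- s$contours[s$contours$structure != "junctions", ]
  expect_error(swept_wall_volumes(s, "LV", 0, 4), class = "svdecomp_input_error")
})

test_that("free-wall sweep volume matches the analytic concentric value", {
  # LV free wall (half circle radius R) moving in by u sweeps
  # (pi/2)(R^2 - (R-u)^2) per unit length
  p <- small_params(lateral_excursion_lv_mm = 5, septal_shift_mm = 0,
                    n_arc_vertices = 64)
  res <- generate_subject(p, seed = 1)
  sw <- swept_wall_volumes(res$study, "LV", 0, res$truth$es_frame, 0.25)
  R <- p$lv_radius_mm + p$wall_mm
  L <- p$n_slices * p$thickness_mm
  analytic <- pi / 2 * (R^2 - (R - 5)^2) * L / 1000
  # exact against the polygonal ground truth; within 2% of the continuum
  # value (the free-wall half-arc carries an O(1/n) polygonization deficit)
  expect_equal(sw$lateral_ml, truth_row(res$truth, "LV")$lateral_ml,
               tolerance = 2e-3)
  expect_equal(sw$lateral_ml, analytic, tolerance = 0.02)
  expect_equal(sw$septal_ml, 0, tolerance = 1e-9)
})

test_that("septal antisymmetry is exact for any study, including noisy ones", {
  for (seed in 1:3) {
    res <- small_subject(seed = seed, noise_sd_mm = if (seed == 3) 0.8 else 0,
                         septal_shift_mm = c(0.5, -0.6, 0.4)[seed])
    es <- res$truth$es_frame
    lv <- swept_wall_volumes(res$study, "LV", 0, es, 0.5)
    rv <- swept_wall_volumes(res$study, "RV", 0, es, 0.5)
    expect_identical(lv$septal_ml, -rv$septal_ml)
  }
})

test_that("decompose_study recovers phantom truth and asserts its identities", {
  res <- small_subject(seed = 2)
  for (vn in c("LV", "RV")) {
    d <- decompose_study(res$study, vn, resolution_mm = 0.25)
    tr <- truth_row(res$truth, vn)
    expect_equal(d$avpd_mm, tr$avpd_mm, tolerance = 1e-12)
    expect_lt(abs(d$longitudinal_pct - tr$longitudinal_pct), 3)
    expect_lt(abs(d$lateral_pct - tr$lateral_pct), 3)
    expect_lt(abs(d$septal_pct - tr$septal_pct), 3)
    # accounting identities hold exactly
    expect_identical(d$radial_ml, d$lateral_ml + d$septal_ml)
    expect_equal(d$longitudinal_pct, 100 * d$longitudinal_ml / d$sv_ml)
    expect_equal(d$qc_sum_pct,
                 d$longitudinal_pct + d$lateral_pct + d$septal_pct)
  }
})

test_that("limit behaviour: piston -> longitudinal 100%; no descent -> 0%", {
  piston <- generate_subject(small_params(lateral_excursion_lv_mm = 0,
                                          lateral_excursion_rv_mm = 0,
                                          septal_shift_mm = 0), seed = 1)
  for (vn in c("LV", "RV")) {
    d <- decompose_study(piston$study, vn)
    expect_lt(abs(d$longitudinal_pct - 100), 2)
    expect_equal(d$lateral_ml, 0, tolerance = 1e-9)
    expect_equal(d$septal_ml, 0, tolerance = 1e-9)
    expect_lt(abs(d$qc_sum_pct - 100), 2)
  }
  concentric <- generate_subject(small_params(avpd_lv_mm = 0, avpd_rv_mm = 0),
                                 seed = 1)
  d0 <- quick_decompose(concentric$study, "LV")
  expect_equal(d0$longitudinal_pct, 0, tolerance = 1e-9)
})

test_that("the summation check warns outside the 90-110% band", {
  res <- small_subject(seed = 1)
  # sabotage the AVP tracks so longitudinal is grossly overestimated
  s <- res$study
  s$avp$position_mm <- s$avp$position_mm * 3
  expect_warning(decompose_study(s, "LV", resolution_mm = 0.5),
                 "summation check")
})

test_that("radial composition and the shared-wall conversion reproduce printed arithmetic", {
  expect_equal(radial_pct(20.3, 3.0), 23.3)
  expect_equal(radial_pct(27.0, 11.0), 38.0)
  expect_equal(radial_pct(5.5, 0), 5.5)
  expect_equal(round(septal_counterpart_pct(-25.4, 52, 120), 1), 11.0)
  expect_equal(septal_counterpart_pct(septal_counterpart_pct(4, 60, 100), 100, 60), 4)
  expect_error(septal_counterpart_pct(5, 50, 0), class = "svdecomp_parameter_error")
})

test_that("tidy and glance expose the decomposition in broom shape", {
  d <- quick_decompose(small_subject(seed = 1)$study, "RV")
  td <- tidy(d)
  expect_identical(td$component, c("longitudinal", "lateral", "septal", "radial"))
  expect_equal(td$pct_of_sv[td$component == "radial"],
               sum(td$pct_of_sv[td$component %in% c("lateral", "septal")]))
  gl <- glance(d)
  expect_identical(nrow(gl), 1L)
  expect_named(gl, c("ventricle", "avpd_mm", "ref_area_mm2", "edv_ml", "esv_ml",
                     "sv_ml", "ef_fraction", "longitudinal_ml", "lateral_ml",
                     "septal_ml", "radial_ml", "longitudinal_pct", "lateral_pct",
                     "septal_pct", "radial_pct", "qc_sum_pct", "ed_frame",
                     "es_frame"))
})
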