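# Calibration of phantom geometry from volumetric targets: given target
# ED volumes, stroke volumes and published contribution percentages, solve
# the phantom's geometric motion parameters so that the generated subject's
# ground truth reproduces the targets (percentages renormalised to sum to
# 100, since the phantom's ground truth is exactly additive while published
# epicardial-method percentages carry the method's summation residual).

#' Calibrate phantom parameters from volumetric targets
#'
#' Solves the phantom's geometric parameters (endocardial radius, crescent
#' apex, AVP descents, free-wall excursions, septal shift) so that the
#' generated ground truth matches prescribed ED/stroke volumes and
#' stroke-volume contribution percentages. LV percentages are renormalised
#' to sum to 100; the RV septal percentage is then fixed by the shared-wall
#' antisymmetry (same septal volume, opposite sign, divided by RVSV) and the
#' remaining RV budget is split between longitudinal and lateral in the
#' prescribed ratio. Solutions use the same polygon builders as the
#' generator, so targets are met to root-finding precision.
#'
#' @param edv_lv_ml,sv_lv_ml LV end-diastolic and stroke volume (mL).
#' @param lv_pct Length-3 vector: LV longitudinal, lateral, septal
#'   contributions in percent of LVSV (any overall scale).
#' @param edv_rv_ml,sv_rv_ml RV end-diastolic and stroke volume (mL).
#' @param rv_long_lat_pct Length-2 vector: RV longitudinal and lateral
#'   contributions in percent of RVSV (only their ratio is used).
#' @param rf_target,tr_target,thv_ml Passed through to [phantom_params()].
#' @param wall_mm,rv_wall_mm Wall thicknesses (mm).
#' @param ... Further arguments for [phantom_params()] (frame/slice layout,
#'   noise, seed, ...).
#' @return A [phantom_params()] object.
#' @export
calibrate_phantom_params <- function(edv_lv_ml, sv_lv_ml, lv_pct,
                                     edv_rv_ml, sv_rv_ml, rv_long_lat_pct,
                                     rf_target = 0, tr_target = 0,
                                     thv_ml = 500, wall_mm = 8, rv_wall_mm = 4,
                                     ...) {
  extra <- list(...)
  layout <- phantom_params() # defaults for the stack layout
  for (nm in intersect(names(extra),
                       c("n_frames", "dt_ms", "n_slices", "thickness_mm",
                         "gap_mm", "n_arc_vertices", "es_frame"))) {
    layout[[nm]] <- extra[[nm]]
  }
  n_arc <- layout$n_arc_vertices
  dz <- layout$thickness_mm + layout$gap_mm
  L <- layout$n_slices * dz

  f_lv <- lv_pct / sum(lv_pct) # renormalised fractions of LVSV

  # LV geometry
  r_lv <- sqrt(edv_lv_ml * 1000 / (L * pi))
  r_sep_ed <- r_lv + wall_mm
  a_epi_lv <- polygon_area(lv_epi_polygon(r_sep_ed, r_sep_ed, n_arc))
  avpd_lv <- f_lv[1L] * sv_lv_ml * 1000 / a_epi_lv

  # septal shift from the shared septal swept area (positive toward LV)
  q_area <- f_lv[3L] * sv_lv_ml * 1000 / L
  c_sep <- septal_sweep_area(1, 0, n_arc) # quad area scales with R^2 - r^2
  r_sep_es_sq <- r_sep_ed^2 - q_area / c_sep
  if (r_sep_es_sq <= 1) {
    abort("septal target exceeds the feasible swept area",
          class = "svdecomp_parameter_error")
  }
  r_sep_es <- sqrt(r_sep_es_sq)
  septal_shift <- r_sep_ed - r_sep_es

  # LV free-wall excursion, solved from the exact ground-truth expression
  # lateral = (area_ED - area_ES) - septal_quad (the ED area keeps the septal
  # chain at its ED radius, so the junction connector wedge is accounted for)
  lat_area_lv <- f_lv[2L] * sv_lv_ml * 1000 / L
  g <- function(r_free) {
    (a_epi_lv - polygon_area(lv_epi_polygon(r_free, r_sep_es, n_arc))) -
      q_area - lat_area_lv
  }
  sol <- uniroot(g, c(0.2, 3 * r_sep_ed), tol = 1e-12)
  lateral_lv <- r_sep_ed - sol$root

  # RV geometry
  a_rv_endo <- edv_rv_ml * 1000 / L
  apex_rv <- solve_rv_apex(r_sep_ed, a_rv_endo, n_arc)
  if (is.na(apex_rv)) {
    abort("RV end-diastolic volume target is not reachable for this septum",
          class = "svdecomp_parameter_error")
  }
  apex_epi <- apex_rv + rv_wall_mm
  a_epi_rv <- polygon_area(rv_region_polygon(r_sep_ed, apex_epi, n_arc))

  f_sep_rv <- -(q_area * L / 1000) / sv_rv_ml
  rem <- 1 - f_sep_rv
  w <- rv_long_lat_pct / sum(rv_long_lat_pct)
  f_long_rv <- rem * w[1L]
  f_lat_rv <- rem * w[2L]
  avpd_rv <- f_long_rv * sv_rv_ml * 1000 / a_epi_rv

  lat_area_rv <- f_lat_rv * sv_rv_ml * 1000 / L
  h <- function(u) {
    (a_epi_rv - polygon_area(rv_region_polygon(r_sep_es, apex_epi - u, n_arc)) +
       q_area) - lat_area_rv
  }
  u_hi <- apex_epi - r_sep_es - 0.6
  sol_rv <- uniroot(h, c(-apex_epi, u_hi), tol = 1e-12)

  args <- c(
    list(
      lv_radius_mm = r_lv, wall_mm = wall_mm, rv_wall_mm = rv_wall_mm,
      rv_crescent_outer_mm = apex_rv,
      avpd_lv_mm = avpd_lv, avpd_rv_mm = avpd_rv,
      lateral_excursion_lv_mm = lateral_lv,
      lateral_excursion_rv_mm = sol_rv$root,
      septal_shift_mm = septal_shift,
      rf_target = rf_target, tr_target = tr_target, thv_ml = thv_ml
    ),
    extra
  )
  do.call(phantom_params, args)
}

#' Phantom presets emulating the porcine study groups
#'
#' Loads one of the preset target files shipped with the package
#' (`inst/extdata/presets/`) and calibrates phantom parameters to it. The
#' presets target the published group means of the porcine
#' pulmonary-regurgitation model (control, PR, PPVR) — ED volumes, stroke
#' volumes, contribution percentages, regurgitant fraction and THV. They are
#' emulation targets for synthetic data, not measurements.
#'
#' @param name `"control"`, `"pr"` or `"ppvr"`.
#' @param ... Overrides passed to [calibrate_phantom_params()] /
#'   [phantom_params()] (e.g. `noise_sd_mm`, `n_arc_vertices`, `seed`).
#' @return A [phantom_params()] object.
#' @export
phantom_preset <- function(name = c("control", "pr", "ppvr"), ...) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "svdecomp", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  tg <- y$targets
  args <- c(
    list(
      edv_lv_ml = tg$edv_lv_ml, sv_lv_ml = tg$sv_lv_ml,
      lv_pct = unlist(tg$lv_pct),
      edv_rv_ml = tg$edv_rv_ml, sv_rv_ml = tg$sv_rv_ml,
      rv_long_lat_pct = unlist(tg$rv_long_lat_pct),
      rf_target = tg$rf_target, tr_target = tg$tr_target,
      thv_ml = tg$thv_ml
    ),
    y$base,
    list(...)
  )
  args <- args[!duplicated(names(args), fromLast = TRUE)]
  do.call(calibrate_phantom_params, args)
}
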