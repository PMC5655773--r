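# Synthetic cine phantom: a cylindrical two-ventricle stack with prescribed
# longitudinal (AVP descent), lateral (free-wall) and septal motion, emitted
# in the package's study format together with analytically known ground truth.
#
# Cross-section template (every slice identical):
#   * LV endocardium: regular polygon of exact prescribed area, centred at the
#     origin.
#   * LV epicardium: left (free-wall) half-arc of radius R_f(t) plus septal
#     half-arc of radius R_c(t); the two junction points (0, +/-R_c(t)) are
#     shared vertices with the RV contours.
#   * RV: crescent between the septal arc and an outer arc through the
#     junctions with apex on the +x axis (endo and epi apices differ by the
#     free-wall thickness).
# Motion: a systolic half-cosine s(t) from 0 (ED, frame 0) to 1 (ES) and back;
# free-wall and septal arcs offset concentrically; the AVP descends by
# avpd * s(t) and the basal cavity is truncated accordingly (fully vacated
# slices lose their endocardial contour; the partially vacated slice carries
# an area-scaled contour so slice summation reproduces the continuum volume).

# Run code with a private, restored RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# --- arc/polygon builders ---------------------------------------------------

# Septal chain: half-arc of radius r through the junctions (0, +/-r),
# sampled bottom-to-top (CCW for the LV region), endpoints included.
septal_chain <- function(r, n) {
  th <- seq(-pi / 2, pi / 2, length.out = n + 1L)
  cbind(r * cos(th), r * sin(th))
}

# LV epicardium: free-wall half-arc radius r_free (x < 0) + septal chain
# radius r_sep; junctions (0, +/-r_sep) are vertices. CCW.
lv_epi_polygon <- function(r_free, r_sep, n) {
  chain <- septal_chain(r_sep, n)
  th <- seq(pi / 2, 3 * pi / 2, length.out = n + 1L)[2:n] # endpoints excluded
  left <- cbind(r_free * cos(th), r_free * sin(th))
  rbind(chain, left)
}

# Outer RV arc through (0, +/-anchor) with apex (apex, 0), sampled from angle
# -phi..+phi about its own centre; endpoints excluded (shared with the chain).
rv_outer_arc <- function(anchor, apex, n) {
  c0 <- (apex^2 - anchor^2) / (2 * apex)
  rho <- apex - c0
  phi <- atan2(anchor, -c0)
  th <- seq(-phi, phi, length.out = n + 1L)[2:n]
  cbind(c0 + rho * cos(th), rho * sin(th))
}

# RV region: septal chain (top to bottom) + outer arc (bottom to top). CCW.
rv_region_polygon <- function(r_sep, apex, n) {
  chain <- septal_chain(r_sep, n)
  rbind(chain[rev(seq_len(nrow(chain))), , drop = FALSE],
        rv_outer_arc(r_sep, apex, n))
}

# Swept-area of the septal arc between two radii: shoelace of the quad formed
# by the ED chain and the reversed ES chain. Positive toward the LV lumen.
septal_sweep_area <- function(r_sep_ed, r_sep_es, n) {
  ed <- septal_chain(r_sep_ed, n)
  es <- septal_chain(r_sep_es, n)
  polygon_area_signed(rbind(ed, es[rev(seq_len(nrow(es))), , drop = FALSE]))
}

# Solve the RV outer-arc apex giving a prescribed crescent area.
solve_rv_apex <- function(r_sep, area, n, lower = NULL, upper = 500) {
  lower <- if (is.null(lower)) r_sep * 1.0005 else lower
  f <- function(a) polygon_area(rv_region_polygon(r_sep, a, n)) - area
  if (f(lower) > 0 || f(upper) < 0) return(NA_real_)
  uniroot(f, c(lower, upper), tol = 1e-12)$root
}

# Scale a polygon about its centroid so its area is multiplied by `factor`.
scale_polygon_area <- function(xy, factor) {
  ctr <- polygon_centroid(xy)
  sweep(sweep(xy, 2L, ctr, "-") * sqrt(factor), 2L, ctr, "+")
}

# --- parameters -------------------------------------------------------------

#' Phantom parameters
#'
#' Geometry and motion parameters for one synthetic subject. Defaults emulate
#' a healthy ("control-like") juvenile pig at 25 cine frames of 30 ms and
#' twelve 6 mm short-axis slices; see [phantom_preset()] for presets that
#' target the published group means of the porcine pulmonary-regurgitation
#' model.
#'
#' @param n_frames Number of cine frames (>= 3); frame 0 is end-diastole.
#' @param dt_ms Temporal resolution in ms.
#' @param n_slices Number of short-axis slices (basal slice is 0).
#' @param thickness_mm,gap_mm Slice thickness and inter-slice gap (mm).
#' @param n_arc_vertices Vertices per half-arc; closed contours get twice as
#'   many. Controls polygonization error only.
#' @param es_frame End-systolic frame index; `NULL` places it at 36% of the
#'   cycle (rounded), matching a physiological systolic fraction.
#' @param lv_radius_mm LV endocardial radius at ED.
#' @param wall_mm,rv_wall_mm LV and RV free-wall thickness.
#' @param rv_crescent_outer_mm Apex (x-extent) of the RV endocardial outer arc
#'   at ED.
#' @param avpd_lv_mm,avpd_rv_mm Peak systolic AVP descent per ventricle
#'   (positive toward the apex).
#' @param lateral_excursion_lv_mm,lateral_excursion_rv_mm Peak inward
#'   free-wall excursion.
#' @param septal_shift_mm Peak septal arc displacement; positive toward the
#'   LV lumen (normal motion), negative toward the RV (paradoxical motion).
#' @param rf_target Pulmonary regurgitant fraction in `[0, 1)`.
#' @param tr_target Tricuspid regurgitant fraction of RVSV in `[0, 1)`.
#' @param flow_dt_ms Sampling interval of the emitted flow curve.
#' @param thv_ml Delineated total heart volume (mL) recorded in the study
#'   metadata; used for THV indexing only.
#' @param noise_sd_mm SD of Gaussian jitter added to every contour and
#'   junction vertex (0 = exact analytic shapes).
#' @param seed Optional default RNG seed used by [generate_subject()] when no
#'   seed is passed there.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(n_frames = 25L, dt_ms = 30, n_slices = 12L,
                           thickness_mm = 6, gap_mm = 0,
                           n_arc_vertices = 48L, es_frame = NULL,
                           lv_radius_mm = 21.6, wall_mm = 8, rv_wall_mm = 4,
                           rv_crescent_outer_mm = 55,
                           avpd_lv_mm = 16.9, avpd_rv_mm = 14.5,
                           lateral_excursion_lv_mm = 2.1,
                           lateral_excursion_rv_mm = 4.5,
                           septal_shift_mm = 0.3,
                           rf_target = 0.013, tr_target = 0,
                           flow_dt_ms = 24, thv_ml = 490.7,
                           noise_sd_mm = 0, seed = NULL) {
  p <- list(
    n_frames = as.integer(n_frames), dt_ms = dt_ms,
    n_slices = as.integer(n_slices),
    thickness_mm = thickness_mm, gap_mm = gap_mm,
    n_arc_vertices = as.integer(n_arc_vertices),
    es_frame = if (is.null(es_frame)) as.integer(round(0.36 * (n_frames - 1L))) else as.integer(es_frame),
    lv_radius_mm = lv_radius_mm, wall_mm = wall_mm, rv_wall_mm = rv_wall_mm,
    rv_crescent_outer_mm = rv_crescent_outer_mm,
    avpd_lv_mm = avpd_lv_mm, avpd_rv_mm = avpd_rv_mm,
    lateral_excursion_lv_mm = lateral_excursion_lv_mm,
    lateral_excursion_rv_mm = lateral_excursion_rv_mm,
    septal_shift_mm = septal_shift_mm,
    rf_target = rf_target, tr_target = tr_target,
    flow_dt_ms = flow_dt_ms, thv_ml = thv_ml,
    noise_sd_mm = noise_sd_mm, seed = seed
  )
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  bad <- function(msg) abort(msg, class = "svdecomp_parameter_error")
  if (p$n_frames < 3L) bad("n_frames must be >= 3")
  if (p$es_frame < 1L || p$es_frame >= p$n_frames) {
    bad("es_frame must lie strictly inside the cycle")
  }
  for (field in c("dt_ms", "n_slices", "thickness_mm", "lv_radius_mm",
                  "wall_mm", "rv_wall_mm", "rv_crescent_outer_mm",
                  "flow_dt_ms", "thv_ml")) {
    if (!is.finite(p[[field]]) || p[[field]] <= 0) {
      bad(sprintf("%s must be > 0", field))
    }
  }
  if (p$gap_mm < 0) bad("gap_mm must be >= 0")
  if (p$noise_sd_mm < 0) bad("noise_sd_mm must be >= 0")
  if (p$rf_target < 0 || p$rf_target >= 1) bad("rf_target must be in [0, 1)")
  if (p$tr_target < 0 || p$tr_target >= 1) bad("tr_target must be in [0, 1)")
  r_sep_ed <- p$lv_radius_mm + p$wall_mm
  if (p$rv_crescent_outer_mm <= r_sep_ed) {
    bad("rv_crescent_outer_mm must exceed the LV epicardial radius (walls overlap)")
  }
  dz <- p$thickness_mm + p$gap_mm
  L <- p$n_slices * dz
  if (p$avpd_lv_mm >= L - dz || p$avpd_rv_mm >= L - dz) {
    bad("AVP descent must leave at least one basal slice occupied at ES")
  }
  if (p$avpd_lv_mm < 0 || p$avpd_rv_mm < 0) bad("AVP descent must be >= 0")
  invisible(p)
}

# --- subject generation -----------------------------------------------------

#' Generate one synthetic subject
#'
#' Builds a complete [cine_study()] (contours, junctions, AVP landmark
#' tracks, pulmonary flow curve, metadata) from phantom parameters, together
#' with its ground truth. The ground truth is computed from the very polygons
#' that are emitted (before any noise), so the accounting closure
#' `longitudinal + lateral + septal = SV` and the LV/RV septal antisymmetry
#' hold to machine precision, and the end-systolic endocardial geometry is
#' solved so the delineated stroke volume equals that sum exactly.
#'
#' @param params A [phantom_params()] object.
#' @param seed RNG seed for contour noise (only used when
#'   `params$noise_sd_mm > 0`); falls back to `params$seed`, else the current
#'   RNG state.
#' @param subject_id,group,covariates Metadata stored in the study.
#' @param validate Validate the emitted study (slower; default `FALSE`
#'   because generated studies are valid by construction — the property is
#'   covered by the test-suite).
#' @return A list with elements `study` ([cine_study()]) and `truth`
#'   ([phantom_truth]).
#' @export
generate_subject <- function(params, seed = NULL, subject_id = "phantom",
                             group = "control", covariates = list(),
                             validate = FALSE) {
  stopifnot(inherits(params, "phantom_params"))
  validate_phantom_params(params)
  seed <- if (is.null(seed)) params$seed else seed
  build <- function() build_subject(params, subject_id, group, covariates, validate)
  if (!is.null(seed)) local_seed(seed, build()) else build()
}

build_subject <- function(p, subject_id, group, covariates, validate) {
  n_arc <- p$n_arc_vertices
  dz <- p$thickness_mm + p$gap_mm
  L <- p$n_slices * dz
  times <- (seq_len(p$n_frames) - 1L) * p$dt_ms
  t_es <- p$es_frame * p$dt_ms
  t_end <- p$n_frames * p$dt_ms
  s <- ifelse(times <= t_es,
              (1 - cos(pi * times / t_es)) / 2,
              (1 + cos(pi * (times - t_es) / (t_end - t_es))) / 2)

  # --- ED cross-section ------------------------------------------------------
  r_sep_ed <- p$lv_radius_mm + p$wall_mm
  a_lv_endo_ed <- polygon_area(circle_polygon_exact_area(
    pi * p$lv_radius_mm^2, 2L * n_arc
  )) # regular polygon inscribed to prescribed circle area
  lv_endo_ed <- circle_polygon_exact_area(a_lv_endo_ed, 2L * n_arc,
                                          phase = pi / (2 * n_arc))
  lv_epi_ed <- lv_epi_polygon(r_sep_ed, r_sep_ed, n_arc)
  a_lv_epi_ed <- polygon_area(lv_epi_ed)
  rv_endo_ed <- rv_region_polygon(r_sep_ed, p$rv_crescent_outer_mm, n_arc)
  a_rv_endo_ed <- polygon_area(rv_endo_ed)
  a_rv_epi_apex_ed <- p$rv_crescent_outer_mm + p$rv_wall_mm
  rv_epi_ed <- rv_region_polygon(r_sep_ed, a_rv_epi_apex_ed, n_arc)
  a_rv_epi_ed <- polygon_area(rv_epi_ed)

  # --- ES epicardial cross-section and ground-truth components --------------
  r_free_es <- r_sep_ed - p$lateral_excursion_lv_mm
  r_sep_es <- r_sep_ed - p$septal_shift_mm
  if (r_free_es <= 1 || r_sep_es <= 1) {
    abort("excursions collapse the LV epicardium (walls overlap)",
          class = "svdecomp_parameter_error")
  }
  lv_epi_es <- lv_epi_polygon(r_free_es, r_sep_es, n_arc)
  a_epi_apex_es <- a_rv_epi_apex_ed - p$lateral_excursion_rv_mm
  if (a_epi_apex_es <= r_sep_es + 0.5) {
    abort("RV free-wall excursion collapses the crescent (walls overlap)",
          class = "svdecomp_parameter_error")
  }
  rv_epi_es <- rv_region_polygon(r_sep_es, a_epi_apex_es, n_arc)

  q_sep <- septal_sweep_area(r_sep_ed, r_sep_es, n_arc) # toward LV lumen, mm^2
  lat_lv_area <- (a_lv_epi_ed - polygon_area(lv_epi_es)) - q_sep
  lat_rv_area <- (a_rv_epi_ed - polygon_area(rv_epi_es)) + q_sep

  truth_lv <- list(
    longitudinal = p$avpd_lv_mm * a_lv_epi_ed / 1000,
    lateral = lat_lv_area * L / 1000,
    septal = q_sep * L / 1000
  )
  truth_rv <- list(
    longitudinal = p$avpd_rv_mm * a_rv_epi_ed / 1000,
    lateral = lat_rv_area * L / 1000,
    septal = -q_sep * L / 1000
  )
  sv_lv <- truth_lv$longitudinal + truth_lv$lateral + truth_lv$septal
  sv_rv <- truth_rv$longitudinal + truth_rv$lateral + truth_rv$septal
  edv_lv <- a_lv_endo_ed * L / 1000
  edv_rv <- a_rv_endo_ed * L / 1000
  esv_lv <- edv_lv - sv_lv
  esv_rv <- edv_rv - sv_rv
  if (esv_lv <= 0 || esv_rv <= 0 || sv_lv <= 0 || sv_rv <= 0) {
    abort("prescribed motion ejects more than the end-diastolic volume",
          class = "svdecomp_parameter_error")
  }

  # ES endocardial geometry solved for exact closure
  a_lv_endo_es <- esv_lv * 1000 / (L - p$avpd_lv_mm)
  r_lv_endo_es <- sqrt(2 * a_lv_endo_es / (2 * n_arc * sin(pi / n_arc)))
  if (r_lv_endo_es >= min(r_free_es, r_sep_es) * cos(pi / (2 * n_arc)) - 0.2) {
    abort("LV endocardium does not fit inside the epicardium at ES (walls overlap)",
          class = "svdecomp_parameter_error")
  }
  a_rv_endo_es <- esv_rv * 1000 / (L - p$avpd_rv_mm)
  apex_rv_endo_es <- solve_rv_apex(r_sep_es, a_rv_endo_es, n_arc)
  if (is.na(apex_rv_endo_es) || apex_rv_endo_es >= a_epi_apex_es - 0.1) {
    abort("RV endocardium does not fit inside the epicardium at ES (walls overlap)",
          class = "svdecomp_parameter_error")
  }

  # --- per-frame contours ----------------------------------------------------
  d_lv <- p$avpd_lv_mm * s
  d_rv <- p$avpd_rv_mm * s
  a_lv_endo_t <- a_lv_endo_ed + (a_lv_endo_es - a_lv_endo_ed) * s
  apex_rv_endo_t <- p$rv_crescent_outer_mm +
    (apex_rv_endo_es - p$rv_crescent_outer_mm) * s
  r_free_t <- r_sep_ed - p$lateral_excursion_lv_mm * s
  r_sep_t <- r_sep_ed - p$septal_shift_mm * s
  apex_epi_t <- a_rv_epi_apex_ed - p$lateral_excursion_rv_mm * s

  rows <- vector("list", p$n_frames)
  for (j in seq_len(p$n_frames)) {
    fr <- j - 1L
    lv_endo <- circle_polygon_exact_area(a_lv_endo_t[j], 2L * n_arc,
                                         phase = pi / (2 * n_arc))
    lv_epi <- lv_epi_polygon(r_free_t[j], r_sep_t[j], n_arc)
    rv_endo <- rv_region_polygon(r_sep_t[j], apex_rv_endo_t[j], n_arc)
    rv_epi <- rv_region_polygon(r_sep_t[j], apex_epi_t[j], n_arc)
    junctions <- rbind(c(0, r_sep_t[j]), c(0, -r_sep_t[j]))

    frame_rows <- vector("list", p$n_slices)
    for (i in seq_len(p$n_slices)) {
      sl <- i - 1L
      polys <- list(lv_epi = lv_epi, rv_epi = rv_epi, junctions = junctions)
      # endocardial truncation by AVP descent
      vac_lv <- d_lv[j] / dz
      vac_rv <- d_rv[j] / dz
      add_endo <- function(name, poly, vac) {
        n_full <- floor(vac + 1e-12)
        if (sl > n_full) {
          polys[[name]] <<- poly
        } else if (sl == n_full) {
          frac <- 1 - (vac - n_full)
          # a residual sliver smaller than the delineation noise would not be
          # traced (and could not be traced reliably); noise-free phantoms
          # keep every sliver so closure stays exact
          r_eff <- sqrt(frac * polygon_area(poly) / pi)
          if (frac > 1e-9 && r_eff >= 3 * p$noise_sd_mm) {
            polys[[name]] <<- scale_polygon_area(poly, frac)
          }
        } # slices below n_full are vacated
      }
      add_endo("lv_endo", lv_endo, vac_lv)
      add_endo("rv_endo", rv_endo, vac_rv)

      frame_rows[[i]] <- dplyr::bind_rows(lapply(names(polys), function(st) {
        v <- polys[[st]]
        tibble(frame = fr, time_ms = times[j], slice = sl,
               thickness_mm = p$thickness_mm, gap_mm = p$gap_mm,
               structure = st, vertex = seq_len(nrow(v)),
               x_mm = v[, 1L], y_mm = v[, 2L])
      }))
    }
    rows[[j]] <- dplyr::bind_rows(frame_rows)
  }
  contours <- dplyr::bind_rows(rows)
  if (p$noise_sd_mm > 0) {
    # Delineation error is spatially smooth (a mistraced border wanders
    # coherently; it does not jump per vertex): each structure on each
    # frame/slice is displaced by an independent random smooth 2-D field
    # (sum of low-frequency sinusoids, wavelengths 25-80 mm) whose pointwise
    # SD is noise_sd_mm. Smoothness keeps jittered contours simple even at
    # the thin crescent tips.
    key <- paste(contours$frame, contours$slice, contours$structure)
    for (g in unique(key)) {
      idx <- which(key == g)
      px <- contours$x_mm[idx]
      py <- contours$y_mm[idx]
      for (coord in c("x_mm", "y_mm")) {
        k_modes <- 6L
        amp <- p$noise_sd_mm * sqrt(2 / k_modes)
        disp <- 0
        for (k in seq_len(k_modes)) {
          th <- stats::runif(1L, 0, 2 * pi)
          omega <- stats::runif(1L, 2 * pi / 80, 2 * pi / 25)
          phase <- stats::runif(1L, 0, 2 * pi)
          disp <- disp + amp * sin(omega * (px * cos(th) + py * sin(th)) + phase)
        }
        contours[[coord]][idx] <- contours[[coord]][idx] + disp
      }
    }
  }

  # --- AVP landmark tracks ---------------------------------------------------
  n_land <- 7L
  offsets <- seq(-3, 3, length.out = n_land)
  avp <- tidyr::expand_grid(
    ventricle = c("LV", "RV"),
    landmark_id = sprintf("m%d", seq_len(n_land)),
    frame = seq.int(0L, p$n_frames - 1L)
  )
  avp$time_ms <- times[avp$frame + 1L]
  base <- offsets[as.integer(sub("m", "", avp$landmark_id))]
  avp$position_mm <- base +
    ifelse(avp$ventricle == "LV", d_lv[avp$frame + 1L], d_rv[avp$frame + 1L])
  avp <- avp[, c("frame", "time_ms", "ventricle", "landmark_id", "position_mm")]

  # --- pulmonary flow curve --------------------------------------------------
  forward_ml <- sv_rv * (1 - p$tr_target)
  retro_ml <- p$rf_target * forward_ml
  ft <- seq(0, t_end, by = p$flow_dt_ms)
  fwd_shape <- ifelse(ft <= t_es, sin(pi * ft / t_es), 0)
  ret_shape <- ifelse(ft > t_es, sin(pi * (ft - t_es) / (t_end - t_es)), 0)
  unit_f <- trapz(ft / 1000, fwd_shape)
  unit_r <- trapz(ft / 1000, ret_shape)
  flow <- tibble(
    time_ms = ft,
    flow_ml_s = (forward_ml / unit_f) * fwd_shape - (retro_ml / unit_r) * ret_shape
  )

  study <- cine_study(
    subject_id = subject_id, group = group, contours = contours,
    avp = avp, flow = flow, thv_ml = p$thv_ml, covariates = covariates,
    validate = validate
  )

  vent <- tibble(
    ventricle = c("LV", "RV"),
    edv_ml = c(edv_lv, edv_rv),
    esv_ml = c(esv_lv, esv_rv),
    sv_ml = c(sv_lv, sv_rv),
    ef_fraction = c(sv_lv / edv_lv, sv_rv / edv_rv),
    avpd_mm = c(p$avpd_lv_mm, p$avpd_rv_mm),
    longitudinal_ml = c(truth_lv$longitudinal, truth_rv$longitudinal),
    lateral_ml = c(truth_lv$lateral, truth_rv$lateral),
    septal_ml = c(truth_lv$septal, truth_rv$septal)
  )
  vent$longitudinal_pct <- 100 * vent$longitudinal_ml / vent$sv_ml
  vent$lateral_pct <- 100 * vent$lateral_ml / vent$sv_ml
  vent$septal_pct <- 100 * vent$septal_ml / vent$sv_ml
  vent$radial_pct <- vent$lateral_pct + vent$septal_pct

  truth <- structure(
    list(
      ventricles = vent,
      rf_pct = 100 * p$rf_target,
      tr_pct = 100 * p$tr_target,
      forward_ml = forward_ml,
      net_forward_ml = forward_ml - retro_ml,
      rvef_corr_pct = 100 * (forward_ml - retro_ml) / edv_rv,
      thv_ml = p$thv_ml,
      es_frame = p$es_frame
    ),
    class = "phantom_truth"
  )
  list(study = study, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth>\n")
  print(x$ventricles)
  cat(sprintf("  RF %.1f%% | TR %.1f%% | corrected RVEF %.1f%% | THV %.1f mL\n",
              x$rf_pct, x$tr_pct, x$rvef_corr_pct, x$thv_ml))
  invisible(x)
}

#' @export
tidy.phantom_truth <- function(x, ...) {
  out <- tidyr::pivot_longer(x$ventricles, -"ventricle",
                             names_to = "quantity", values_to = "value")
  dplyr::bind_rows(out, tibble(
    ventricle = NA_character_,
    quantity = c("rf_pct", "tr_pct", "rvef_corr_pct", "thv_ml"),
    value = c(x$rf_pct, x$tr_pct, x$rvef_corr_pct, x$thv_ml)
  ))
}
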