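#' Area enclosed by a contour
#'
#' Absolute shoelace area of a closed polygonal contour, independent of
#' vertex orientation and starting vertex.
#'
#' @param contour Two-column matrix or data frame of `(x_mm, y_mm)` vertices.
#' @return Area in mm^2.
#' @export
contour_area <- function(contour) {
  xy <- as.matrix(contour)
  if (nrow(xy) < 3L) {
    abort("a contour needs at least 3 vertices", class = "svdecomp_contour_error")
  }
  a <- polygon_area(xy)
  if (a <= 0) {
    abort("degenerate contour: enclosed area is zero",
          class = "svdecomp_contour_error")
  }
  a
}

#' Slice-summation volume of one structure at one frame
#'
#' Sums contour area times slice increment (thickness + gap) over all slices
#' where the structure is delineated at the given frame — the standard
#' short-axis slice-summation (Simpson) volumetry.
#'
#' @param study A [cine_study()].
#' @param frame Frame index.
#' @param structure One of `"lv_endo"`, `"lv_epi"`, `"rv_endo"`, `"rv_epi"`.
#' @return Volume in mL.
#' @export
stack_volume <- function(study, frame, structure) {
  k <- study$contours
  rows <- k$frame == frame & k$structure == structure
  if (!any(rows)) {
    abort(sprintf("structure '%s' absent on every slice of frame %d",
                  structure, frame),
          class = "svdecomp_contour_error")
  }
  sub <- k[rows, , drop = FALSE]
  per_slice <- dplyr::group_by(sub, .data$slice, .data$thickness_mm, .data$gap_mm)
  per_slice <- dplyr::summarise(
    per_slice,
    area_mm2 = polygon_area(cbind(.data$x_mm[order(.data$vertex)],
                                  .data$y_mm[order(.data$vertex)])),
    .groups = "drop"
  )
  sum(per_slice$area_mm2 * (per_slice$thickness_mm + per_slice$gap_mm)) / 1000
}

#' Ventricular volume curve, ED/ES and ejection fraction
#'
#' Computes the endocardial slice-summation volume at every frame,
#' identifies end-diastole (fixed at frame 0, the gated acquisition
#' convention; a warning is raised when a later frame is larger) and
#' end-systole (the frame of minimum volume), and derives stroke volume and
#' ejection fraction.
#'
#' @param study A [cine_study()].
#' @param ventricle `"LV"` or `"RV"`.
#' @return An object of class `svd_volumes` with fields `ventricle`, `curve`
#'   (per-frame tibble), `edv_ml`, `esv_ml`, `sv_ml`, `ef_fraction`,
#'   `ed_frame`, `es_frame`. `tidy()` returns the per-frame curve, `glance()`
#'   the scalars.
#' @export
ventricular_volumes <- function(study, ventricle = c("LV", "RV")) {
  ventricle <- match.arg(ventricle)
  structure <- if (ventricle == "LV") "lv_endo" else "rv_endo"
  ft <- study_frame_times(study)
  if (nrow(ft) == 0L) {
    abort("study has no frames", class = "svdecomp_contour_error")
  }
  vol <- vapply(ft$frame, function(fr) stack_volume(study, fr, structure),
                numeric(1L))
  curve <- tibble(frame = ft$frame, time_ms = ft$time_ms, volume_ml = vol)

  ed_frame <- 0L
  edv <- curve$volume_ml[curve$frame == 0L]
  if (any(curve$volume_ml > edv + 1e-9)) {
    warn(sprintf(
      "%s volume exceeds the frame-0 value later in the cycle (max %.1f vs %.1f mL); ED kept at frame 0",
      ventricle, max(curve$volume_ml), edv
    ))
  }
  es_frame <- curve$frame[which.min(curve$volume_ml)]
  esv <- min(curve$volume_ml)
  sv <- edv - esv

  structure(
    list(
      ventricle = ventricle, curve = curve,
      edv_ml = edv, esv_ml = esv, sv_ml = sv,
      ef_fraction = sv / edv,
      ed_frame = ed_frame, es_frame = es_frame
    ),
    class = "svd_volumes"
  )
}

#' @export
print.svd_volumes <- function(x, ...) {
  cat(sprintf(
    "<svd_volumes> %s: EDV %.1f mL (frame %d), ESV %.1f mL (frame %d), SV %.1f mL, EF %.1f%%\n",
    x$ventricle, x$edv_ml, x$ed_frame, x$esv_ml, x$es_frame, x$sv_ml,
    100 * x$ef_fraction
  ))
  invisible(x)
}

#' @export
tidy.svd_volumes <- function(x, ...) {
  dplyr::mutate(x$curve, ventricle = x$ventricle, .before = 1L)
}

#' @export
glance.svd_volumes <- function(x, ...) {
  tibble(
    ventricle = x$ventricle, edv_ml = x$edv_ml, esv_ml = x$esv_ml,
    sv_ml = x$sv_ml, ef_fraction = x$ef_fraction,
    ed_frame = x$ed_frame, es_frame = x$es_frame
  )
}

#' Index a volume to total heart volume
#'
#' Expresses a chamber volume as a percentage of the subject's total heart
#' volume (THV), the size normalisation used to compare animals of different
#' growth stages (THV is near-constant over the cardiac cycle).
#'
#' @param volume_ml Chamber volume (mL).
#' @param thv_ml Total heart volume (mL, > 0).
#' @return Percentage of THV.
#' @export
index_to_thv <- function(volume_ml, thv_ml) {
  if (any(!is.finite(thv_ml)) || any(thv_ml <= 0)) {
    abort("thv_ml must be > 0", class = "svdecomp_parameter_error")
  }
  100 * volume_ml / thv_ml
}
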