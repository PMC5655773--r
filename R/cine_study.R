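#' Assemble a cine study
#'
#' A `cine_study` bundles everything the pipeline needs for one subject: the
#' time-resolved short-axis segmentation contours, the long-axis
#' atrioventricular-plane (AVP) landmark tracks, the pulmonary-artery flow
#' curve, the delineated total heart volume (THV) and optional covariates.
#' All in-plane coordinates are millimetres; slice 0 is the most basal slice
#' and through-plane position is `slice * (thickness_mm + gap_mm)`.
#'
#' @param subject_id Character scalar.
#' @param group One of `"control"`, `"PR"`, `"PPVR"`.
#' @param contours Tibble with columns `frame`, `time_ms`, `slice`,
#'   `thickness_mm`, `gap_mm`, `structure`, `vertex`, `x_mm`, `y_mm`.
#'   `structure` is one of `lv_endo`, `lv_epi`, `rv_endo`, `rv_epi` (polygon
#'   contours, >= 3 vertices, implicitly closed) or `junctions` (exactly two
#'   points marking the anterior and inferior RV-LV insertions).
#' @param avp Tibble with columns `frame`, `time_ms`, `ventricle`
#'   (`"LV"`/`"RV"`), `landmark_id`, `position_mm` (long-axis position,
#'   positive toward the apex).
#' @param flow Tibble with columns `time_ms` (strictly increasing) and
#'   `flow_ml_s` (signed; positive = antegrade into the pulmonary artery).
#' @param thv_ml Delineated total heart volume in mL (> 0).
#' @param covariates Optional named list of scalar covariates
#'   (e.g. `weight_kg`, `pcwp_mmhg`).
#' @param validate Run [validate_study()] and abort on any error-severity
#'   finding (default `TRUE`).
#'
#' @return An object of class `cine_study`.
#' @seealso [validate_study()], [read_cine_study()], [generate_subject()]
#' @export
cine_study <- function(subject_id, group, contours, avp, flow, thv_ml,
                       covariates = list(), validate = TRUE) {
  contours <- as_tibble(contours)
  contours <- contours[order(contours$frame, contours$slice,
                             contours$structure, contours$vertex), , drop = FALSE]
  avp <- as_tibble(avp)
  avp <- avp[order(avp$ventricle, avp$landmark_id, avp$frame), , drop = FALSE]
  study <- structure(
    list(
      subject_id = as.character(subject_id),
      group = as.character(group),
      contours = contours,
      avp = avp,
      flow = as_tibble(flow),
      thv_ml = as.numeric(thv_ml),
      covariates = as.list(covariates)
    ),
    class = "cine_study"
  )
  if (validate) {
    findings <- validate_study(study)
    errs <- findings[findings$severity == "error", , drop = FALSE]
    if (nrow(errs) > 0L) {
      abort(
        c("invalid cine study",
          stats::setNames(paste0(errs$location, ": ", errs$message),
                          rep("x", nrow(errs)))),
        class = "svdecomp_validation_error"
      )
    }
  }
  study
}

#' @export
print.cine_study <- function(x, ...) {
  nf <- length(unique(x$contours$frame))
  ns <- length(unique(x$contours$slice))
  cat(sprintf(
    "<cine_study> subject %s (%s): %d frames x %d slices, THV %.1f mL\n",
    x$subject_id, x$group, nf, ns, x$thv_ml
  ))
  cat(sprintf(
    "  avp: %d landmark tracks | flow: %d samples | covariates: %s\n",
    nrow(dplyr::distinct(x$avp, .data$ventricle, .data$landmark_id)),
    nrow(x$flow),
    if (length(x$covariates)) paste(names(x$covariates), collapse = ", ") else "none"
  ))
  invisible(x)
}

structure_names <- c("lv_endo", "lv_epi", "rv_endo", "rv_epi")
group_names <- c("control", "PR", "PPVR")

# n x 2 vertex matrix for one structure on one frame/slice, or NULL.
study_polygon <- function(study, frame, slice, structure) {
  k <- study$contours
  rows <- k$frame == frame & k$slice == slice & k$structure == structure
  if (!any(rows)) return(NULL)
  sub <- k[rows, , drop = FALSE]
  sub <- sub[order(sub$vertex), , drop = FALSE]
  cbind(sub$x_mm, sub$y_mm)
}

study_junctions <- function(study, frame, slice) {
  study_polygon(study, frame, slice, "junctions")
}

study_frame_times <- function(study) {
  ft <- dplyr::distinct(study$contours, .data$frame, .data$time_ms)
  ft[order(ft$frame), , drop = FALSE]
}

# slice -> thickness + gap lookup (constant across frames once validated)
study_slice_geometry <- function(study) {
  dplyr::distinct(study$contours, .data$slice, .data$thickness_mm, .data$gap_mm)
}

new_finding <- function(severity, location, message) {
  tibble(severity = severity, location = location, message = message)
}

#' Validate a cine study
#'
#' Checks every structural invariant of the data model and returns findings
#' rather than throwing: contour well-formedness (>= 3 vertices, simple,
#' non-degenerate area), slice geometry (positive thickness, non-negative gap,
#' unique contiguous slice indices, geometry shared by all frames),
#' containment of the LV endocardium within the LV epicardium, junction
#' points lying on both epicardial contours (within `junction_tol_mm`),
#' AVP track completeness, flow-curve monotonicity and metadata ranges.
#'
#' @param study A [cine_study()].
#' @param junction_tol_mm Maximum distance (mm) a junction point may lie from
#'   each epicardial contour before a warning finding is issued. Manual
#'   delineations are never exact; the default allows 2 mm.
#' @return A tibble of findings with columns `severity` (`"error"` or
#'   `"warning"`), `location` and `message`; zero rows when every invariant
#'   holds.
#' @export
validate_study <- function(study, junction_tol_mm = 2) {
  f <- list()
  add <- function(sev, loc, msg) f[[length(f) + 1L]] <<- new_finding(sev, loc, msg)
  sid <- study$subject_id

  if (!study$group %in% group_names) {
    add("error", sprintf("subject %s", sid),
        sprintf("group '%s' is not one of %s", study$group,
                paste(group_names, collapse = "/")))
  }
  if (!is.finite(study$thv_ml) || study$thv_ml <= 0) {
    add("error", sprintf("subject %s", sid), "thv_ml must be > 0")
  }

  k <- study$contours
  if (nrow(k) == 0L) {
    add("error", sprintf("subject %s", sid), "study has no frames")
    return(dplyr::bind_rows(f))
  }

  ft <- study_frame_times(study)
  if (any(ft$time_ms < 0)) {
    add("error", sprintf("subject %s", sid), "frame time_ms must be >= 0")
  }

  # slice geometry must be shared by all frames
  geo <- dplyr::distinct(k, .data$slice, .data$thickness_mm, .data$gap_mm)
  if (anyDuplicated(geo$slice)) {
    add("error", sprintf("subject %s", sid),
        "slice thickness/gap differ between frames")
  }
  if (any(geo$thickness_mm <= 0)) {
    add("error", sprintf("subject %s", sid), "thickness_mm must be > 0")
  }
  if (any(geo$gap_mm < 0)) {
    add("error", sprintf("subject %s", sid), "gap_mm must be >= 0")
  }
  slices <- sort(unique(k$slice))
  if (!identical(as.integer(slices), seq.int(0L, length(slices) - 1L))) {
    add("error", sprintf("subject %s", sid),
        "slice indices must be unique and contiguous from 0")
  }

  # row index by (frame, slice, structure) so each contour is fetched once
  key <- paste(k$frame, k$slice, k$structure, sep = "\r")
  idx <- split(seq_len(nrow(k)), key)
  get_poly <- function(fr, sl, st) {
    rows <- idx[[paste(fr, sl, st, sep = "\r")]]
    if (is.null(rows)) return(NULL)
    rows <- rows[order(k$vertex[rows])]
    cbind(k$x_mm[rows], k$y_mm[rows])
  }

  per <- dplyr::distinct(k, .data$frame, .data$slice, .data$structure)
  for (i in seq_len(nrow(per))) {
    fr <- per$frame[i]; sl <- per$slice[i]; st <- per$structure[i]
    loc <- sprintf("subject %s frame %d slice %d %s", sid, fr, sl, st)
    xy <- get_poly(fr, sl, st)
    if (st == "junctions") {
      if (nrow(xy) != 2L) add("error", loc, "junctions must be exactly 2 points")
      next
    }
    if (!st %in% structure_names) {
      add("error", loc, sprintf("unknown structure '%s'", st))
      next
    }
    if (nrow(xy) < 3L) {
      add("error", loc, sprintf("contour has %d vertices; >= 3 required", nrow(xy)))
      next
    }
    if (polygon_area(xy) <= 0) {
      add("error", loc, "contour area is zero (degenerate)")
      next
    }
    if (!polygon_is_simple(xy)) {
      add("error", loc, "contour is self-intersecting")
    }
  }

  # lv_endo inside lv_epi; junctions on both epicardial contours
  both <- dplyr::distinct(k, .data$frame, .data$slice)
  for (i in seq_len(nrow(both))) {
    fr <- both$frame[i]; sl <- both$slice[i]
    endo <- get_poly(fr, sl, "lv_endo")
    epi <- get_poly(fr, sl, "lv_epi")
    if (!is.null(endo) && !is.null(epi) && nrow(endo) >= 3L && nrow(epi) >= 3L) {
      if (!all(points_in_polygon(endo[, 1L], endo[, 2L], epi))) {
        add("error", sprintf("subject %s frame %d slice %d", sid, fr, sl),
            "lv_endo extends outside lv_epi")
      }
    }
    jn <- get_poly(fr, sl, "junctions")
    rv_epi <- get_poly(fr, sl, "rv_epi")
    if (!is.null(jn) && nrow(jn) == 2L && !is.null(epi) && !is.null(rv_epi)) {
      for (j in 1:2) {
        d_lv <- point_polygon_distance(jn[j, 1L], jn[j, 2L], epi)
        d_rv <- point_polygon_distance(jn[j, 1L], jn[j, 2L], rv_epi)
        if (max(d_lv, d_rv) > junction_tol_mm) {
          add("warning", sprintf("subject %s frame %d slice %d", sid, fr, sl),
              sprintf("junction point %d lies %.1f mm from an epicardial contour (tolerance %.1f mm)",
                      j, max(d_lv, d_rv), junction_tol_mm))
        }
      }
    }
  }

  # AVP tracks: every track needs one value per frame
  a <- study$avp
  if (nrow(a) == 0L) {
    add("error", sprintf("subject %s", sid), "no AVP landmark tracks")
  } else {
    if (!all(a$ventricle %in% c("LV", "RV"))) {
      add("error", sprintf("subject %s", sid), "avp ventricle must be LV or RV")
    }
    frames <- ft$frame
    tracks <- dplyr::distinct(a, .data$ventricle, .data$landmark_id)
    for (i in seq_len(nrow(tracks))) {
      have <- a$frame[a$ventricle == tracks$ventricle[i] &
                        a$landmark_id == tracks$landmark_id[i]]
      missing <- setdiff(frames, have)
      if (length(missing)) {
        add("error",
            sprintf("subject %s %s landmark %s", sid, tracks$ventricle[i],
                    tracks$landmark_id[i]),
            sprintf("missing AVP position for frame(s) %s",
                    paste(missing, collapse = ", ")))
      }
      if (anyDuplicated(have)) {
        add("error",
            sprintf("subject %s %s landmark %s", sid, tracks$ventricle[i],
                    tracks$landmark_id[i]),
            "duplicated AVP position for a frame")
      }
    }
  }

  # flow curve
  fl <- study$flow
  if (nrow(fl) < 2L) {
    add("error", sprintf("subject %s flow", sid), "flow curve needs >= 2 samples")
  } else if (any(diff(fl$time_ms) <= 0)) {
    add("error", sprintf("subject %s flow", sid),
        "flow time_ms must be strictly increasing")
  }

  if (length(f)) dplyr::bind_rows(f) else
    tibble(severity = character(), location = character(), message = character())
}
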