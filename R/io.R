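#' Read a cine study from a directory
#'
#' Loads the four files that make up one subject's study and returns a fully
#' validated [cine_study()]:
#'
#' * `contours.jsonl` — one JSON object per line with fields `subject`,
#'   `frame`, `time_ms`, `slice`, `thickness_mm`, `gap_mm`, `structure`
#'   (`lv_endo`/`lv_epi`/`rv_endo`/`rv_epi`/`junctions`) and `vertices`
#'   (`[[x, y], ...]` in mm);
#' * `avp.csv` — columns `frame`, `time_ms`, `ventricle`, `landmark_id`,
#'   `position_mm`;
#' * `flow.csv` — columns `time_ms`, `flow_ml_s`;
#' * `meta.yaml` (or `meta.json`) — `subject_id`, `group`, `thv_ml` and an
#'   optional `covariates` mapping.
#'
#' @param path Directory containing the study files.
#' @param validate Abort on error-severity validation findings (default TRUE).
#' @return A [cine_study()].
#' @export
read_cine_study <- function(path, validate = TRUE) {
  need <- function(fname, alt = NULL) {
    p <- file.path(path, fname)
    if (file.exists(p)) return(p)
    if (!is.null(alt)) {
      p2 <- file.path(path, alt)
      if (file.exists(p2)) return(p2)
      abort(sprintf("study file not found: %s (or %s) in %s", fname, alt, path),
            class = "svdecomp_load_error")
    }
    abort(sprintf("study file not found: %s in %s", fname, path),
          class = "svdecomp_load_error")
  }

  contour_path <- need("contours.jsonl")
  avp_path <- need("avp.csv")
  flow_path <- need("flow.csv")
  meta_path <- need("meta.yaml", "meta.json")

  lines <- readLines(contour_path)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyMatrix = TRUE)
  contours <- dplyr::bind_rows(lapply(recs, function(r) {
    v <- r$vertices
    if (is.null(dim(v))) v <- matrix(v, ncol = 2L, byrow = TRUE)
    tibble(
      frame = as.integer(r$frame), time_ms = as.numeric(r$time_ms),
      slice = as.integer(r$slice), thickness_mm = as.numeric(r$thickness_mm),
      gap_mm = as.numeric(r$gap_mm), structure = as.character(r$structure),
      vertex = seq_len(nrow(v)), x_mm = v[, 1L], y_mm = v[, 2L]
    )
  }))

  avp <- readr::read_csv(avp_path, show_col_types = FALSE,
                         col_types = readr::cols(
                           frame = readr::col_integer(),
                           time_ms = readr::col_double(),
                           ventricle = readr::col_character(),
                           landmark_id = readr::col_character(),
                           position_mm = readr::col_double()
                         ))
  flow <- readr::read_csv(flow_path, show_col_types = FALSE,
                          col_types = readr::cols(
                            time_ms = readr::col_double(),
                            flow_ml_s = readr::col_double()
                          ))
  meta <- if (grepl("\\.json$", meta_path)) {
    jsonlite::fromJSON(meta_path)
  } else {
    yaml::read_yaml(meta_path)
  }
  for (field in c("subject_id", "group", "thv_ml")) {
    if (is.null(meta[[field]])) {
      abort(sprintf("meta file %s is missing field '%s'", meta_path, field),
            class = "svdecomp_load_error")
    }
  }

  cine_study(
    subject_id = meta$subject_id, group = meta$group,
    contours = contours, avp = avp, flow = flow,
    thv_ml = meta$thv_ml,
    covariates = if (is.null(meta$covariates)) list() else meta$covariates,
    validate = validate
  )
}

#' Write a cine study to a directory
#'
#' Serialises a [cine_study()] to the on-disk layout read by
#' [read_cine_study()] (`contours.jsonl`, `avp.csv`, `flow.csv`, `meta.yaml`).
#' The study is validated first and serialisation is refused when any
#' error-severity finding is present; numeric values round-trip to better
#' than 1e-9 mm.
#'
#' @param study A [cine_study()].
#' @param path Output directory (created if necessary).
#' @return `path`, invisibly.
#' @export
write_cine_study <- function(study, path) {
  findings <- validate_study(study)
  errs <- findings[findings$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0L) {
    abort(c("refusing to serialize an invalid study",
            stats::setNames(paste0(errs$location, ": ", errs$message),
                            rep("x", nrow(errs)))),
          class = "svdecomp_validation_error")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) {
    abort(sprintf("cannot create study directory %s", path),
          class = "svdecomp_write_error")
  }

  k <- study$contours
  key <- dplyr::distinct(k, .data$frame, .data$time_ms, .data$slice,
                         .data$thickness_mm, .data$gap_mm, .data$structure)
  key <- key[order(key$frame, key$slice, key$structure), , drop = FALSE]
  lines <- vapply(seq_len(nrow(key)), function(i) {
    rows <- k$frame == key$frame[i] & k$slice == key$slice[i] &
      k$structure == key$structure[i]
    sub <- k[rows, , drop = FALSE]
    sub <- sub[order(sub$vertex), , drop = FALSE]
    jsonlite::toJSON(
      list(
        subject = jsonlite::unbox(study$subject_id),
        frame = jsonlite::unbox(key$frame[i]),
        time_ms = jsonlite::unbox(key$time_ms[i]),
        slice = jsonlite::unbox(key$slice[i]),
        thickness_mm = jsonlite::unbox(key$thickness_mm[i]),
        gap_mm = jsonlite::unbox(key$gap_mm[i]),
        structure = jsonlite::unbox(key$structure[i]),
        vertices = cbind(sub$x_mm, sub$y_mm)
      ),
      digits = NA
    )
  }, character(1L))
  writeLines(lines, file.path(path, "contours.jsonl"))

  readr::write_csv(study$avp, file.path(path, "avp.csv"))
  readr::write_csv(study$flow, file.path(path, "flow.csv"))
  meta <- list(subject_id = study$subject_id, group = study$group,
               thv_ml = study$thv_ml)
  if (length(study$covariates)) meta$covariates <- study$covariates
  yaml::write_yaml(meta, file.path(path, "meta.yaml"), precision = 15L)
  invisible(path)
}
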