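# Hand-built miniature studies with known square contours, for unit tests of
# the volumetry primitives and of validation findings.

square_xy <- function(side, cx = 0, cy = 0) {
  h <- side / 2
  cbind(cx + c(-h, h, h, -h), cy + c(-h, -h, h, h))
}

contour_rows <- function(frame, time_ms, slice, structure, xy,
                         thickness_mm = 6, gap_mm = 0) {
  tibble::tibble(
    frame = frame, time_ms = time_ms, slice = slice,
    thickness_mm = thickness_mm, gap_mm = gap_mm, structure = structure,
    vertex = seq_len(nrow(xy)), x_mm = xy[, 1], y_mm = xy[, 2]
  )
}

# `epi_sides`: list (one element per frame) of numeric vectors of square side
# lengths per slice. Endocardial squares are 4 mm smaller.
toy_study <- function(epi_sides, thickness_mm = 6, gap_mm = 0,
                      thv_ml = 300, validate = TRUE) {
  n_frames <- length(epi_sides)
  rows <- list()
  for (f in seq_len(n_frames)) {
    sides <- epi_sides[[f]]
    for (s in seq_along(sides)) {
      rows <- c(rows, list(
        contour_rows(f - 1L, (f - 1L) * 30, s - 1L, "lv_epi",
                     square_xy(sides[s]), thickness_mm, gap_mm),
        contour_rows(f - 1L, (f - 1L) * 30, s - 1L, "lv_endo",
                     square_xy(sides[s] - 4), thickness_mm, gap_mm)
      ))
    }
  }
  avp <- tidyr::expand_grid(ventricle = c("LV", "RV"),
                            frame = seq.int(0L, n_frames - 1L))
  avp$time_ms <- avp$frame * 30
  avp$landmark_id <- "m1"
  avp$position_mm <- 0
  cine_study(
    subject_id = "toy", group = "control",
    contours = dplyr::bind_rows(rows),
    avp = avp[, c("frame", "time_ms", "ventricle", "landmark_id", "position_mm")],
    flow = tibble::tibble(time_ms = c(0, 300, 600), flow_ml_s = c(0, 100, 0)),
    thv_ml = thv_ml, validate = validate
  )
}
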