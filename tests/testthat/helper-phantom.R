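# Small, fast phantom used by most unit tests: 9 frames, 6 slices, coarse
# polygons. Motion is scaled to the shorter stack so the geometry is
# feasible.
small_params <- function(...) {
  args <- utils::modifyList(
    list(
      n_frames = 9L, n_slices = 6L, n_arc_vertices = 32L,
      avpd_lv_mm = 8, avpd_rv_mm = 7,
      lateral_excursion_lv_mm = 1.5, lateral_excursion_rv_mm = 3,
      septal_shift_mm = 0.3
    ),
    list(...)
  )
  do.call(phantom_params, args)
}

small_subject <- function(seed = 1, ...) {
  generate_subject(small_params(...), seed = seed)
}

# decompose at a coarser raster to keep unit tests quick
quick_decompose <- function(study, ventricle, resolution_mm = 0.5) {
  suppressWarnings(decompose_study(study, ventricle, resolution_mm))
}

truth_row <- function(truth, ventricle) {
  truth$ventricles[truth$ventricles$ventricle == ventricle, , drop = FALSE]
}
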