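#' Per-subject metrics row
#'
#' Runs the full pipeline on one study — volumetry, THV indexing,
#' stroke-volume decomposition for both ventricles and flow analysis — and
#' returns a single tidy row holding every derived quantity plus the
#' subject's covariates. One row per subject is the unit of the group report
#' ([build_group_table()]).
#'
#' @param study A [cine_study()].
#' @param resolution_mm Raster resolution for the swept-wall computation.
#' @param tr_threshold_pct TR detection threshold (% of RVSV).
#' @return A one-row tibble.
#' @export
subject_metrics <- function(study, resolution_mm = 0.25, tr_threshold_pct = 5) {
  lv <- decompose_study(study, "LV", resolution_mm)
  rv <- decompose_study(study, "RV", resolution_mm)
  fm <- flow_metrics(study, rvsv_ml = rv$sv_ml, rvedv_ml = rv$edv_ml,
                     tr_threshold_pct = tr_threshold_pct)

  out <- tibble(
    subject_id = study$subject_id,
    group = study$group,
    thv_ml = study$thv_ml,
    pr_pct = fm$rf_pct,
    lvedv_ml = lv$edv_ml,
    lvedvi_pct = index_to_thv(lv$edv_ml, study$thv_ml),
    lvesv_ml = lv$esv_ml,
    lvesvi_pct = index_to_thv(lv$esv_ml, study$thv_ml),
    lvsv_ml = lv$sv_ml,
    lvef_pct = 100 * lv$ef_fraction,
    lv_longitudinal_pct = lv$longitudinal_pct,
    lv_radial_pct = lv$radial_pct,
    lv_lateral_pct = lv$lateral_pct,
    lv_septal_pct = lv$septal_pct,
    lv_qc_sum_pct = lv$qc_sum_pct,
    rvedv_ml = rv$edv_ml,
    rvedvi_pct = index_to_thv(rv$edv_ml, study$thv_ml),
    rvesv_ml = rv$esv_ml,
    rvesvi_pct = index_to_thv(rv$esv_ml, study$thv_ml),
    rvsv_ml = rv$sv_ml,
    rvef_pct = 100 * rv$ef_fraction,
    rvef_corr_pct = fm$rvef_corr_pct,
    rv_longitudinal_pct = rv$longitudinal_pct,
    rv_radial_pct = rv$radial_pct,
    rv_lateral_pct = rv$lateral_pct,
    rv_septal_pct = rv$septal_pct,
    rv_qc_sum_pct = rv$qc_sum_pct,
    forward_ml = fm$forward_ml,
    net_forward_ml = fm$net_forward_ml,
    tr_volume_ml = fm$tr_volume_ml,
    tr_pct = fm$tr_pct,
    tr_present = fm$tr_present
  )
  cov <- study$covariates
  for (nm in names(cov)) {
    if (is.numeric(cov[[nm]]) || is.logical(cov[[nm]])) out[[nm]] <- cov[[nm]]
  }
  out
}

#' Metrics table for a set of studies
#'
#' @param studies A list of [cine_study()] objects, or a phantom cohort as
#'   returned by [generate_cohort()] (elements with `$study`).
#' @inheritParams subject_metrics
#' @return A tibble with one row per subject.
#' @export
cohort_metrics <- function(studies, resolution_mm = 0.25, tr_threshold_pct = 5) {
  rows <- lapply(studies, function(s) {
    if (!inherits(s, "cine_study") && !is.null(s$study)) s <- s$study
    subject_metrics(s, resolution_mm, tr_threshold_pct)
  })
  dplyr::bind_rows(rows)
}
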