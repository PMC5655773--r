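# Cohort generation: seeded sampling of per-subject phantom parameters
# around group-level means, with an optional covariate model linking PCWP to
# the RV longitudinal contribution (emulating the haemodynamic coupling seen
# in volume-overloaded animals).

#' Group specification for cohort generation
#'
#' @param group Group label (`"control"`, `"PR"`, `"PPVR"`).
#' @param n_subjects Number of subjects (>= 1).
#' @param params A [phantom_params()] object holding the group means.
#' @param sd Named list of between-subject SDs for numeric parameter fields
#'   (parameters not listed are held fixed). Draws are clamped at
#'   mean +/- 2.5 SD and to each parameter's feasible range.
#' @param covariates Optional covariate models: `weight` as
#'   `list(mean, sd)` (kg) and `pcwp` as `list(a, b, sd)` generating
#'   `pcwp_mmhg = a + b * (true RV longitudinal % of RVSV) + noise`.
#' @return An `svd_group_spec`.
#' @export
group_spec <- function(group, n_subjects, params, sd = list(),
                       covariates = list()) {
  if (!group %in% group_names) {
    abort(sprintf("group must be one of %s", paste(group_names, collapse = "/")),
          class = "svdecomp_parameter_error")
  }
  if (n_subjects < 1L) {
    abort("n_subjects must be >= 1", class = "svdecomp_parameter_error")
  }
  stopifnot(inherits(params, "phantom_params"))
  if (length(sd) && (any(!vapply(sd, is.numeric, logical(1L))) ||
                     any(unlist(sd) < 0))) {
    abort("sd entries must be non-negative numbers",
          class = "svdecomp_parameter_error")
  }
  structure(
    list(group = group, n_subjects = as.integer(n_subjects), params = params,
         sd = sd, covariates = covariates),
    class = "svd_group_spec"
  )
}

# Parameter fields that may vary between subjects, with feasibility clamps.
param_clamp <- function(name, value, base) {
  switch(name,
    rf_target = ,
    tr_target = min(max(value, 0), 0.9),
    avpd_lv_mm = ,
    avpd_rv_mm = min(max(value, 0),
                     0.85 * base$n_slices * (base$thickness_mm + base$gap_mm)),
    lv_radius_mm = max(value, 5),
    wall_mm = ,
    rv_wall_mm = max(value, 1),
    rv_crescent_outer_mm = max(value, base$lv_radius_mm + base$wall_mm + 5),
    value
  )
}

draw_params <- function(spec) {
  p <- spec$params
  for (nm in names(spec$sd)) {
    if (!nm %in% names(p) || !is.numeric(p[[nm]])) {
      abort(sprintf("unknown or non-numeric parameter '%s' in sd spec", nm),
            class = "svdecomp_parameter_error")
    }
    s <- spec$sd[[nm]]
    x <- rnorm(1L, p[[nm]], s)
    x <- min(max(x, p[[nm]] - 2.5 * s), p[[nm]] + 2.5 * s)
    p[[nm]] <- param_clamp(nm, x, spec$params)
  }
  validate_phantom_params(p)
  p
}

#' Generate a seeded cohort of synthetic subjects
#'
#' Draws per-subject phantom parameters from each group specification
#' (means + between-subject SDs), generates each subject with
#' [generate_subject()] and emits covariates per the group's covariate
#' model. Deterministic for a fixed seed.
#'
#' @param specs A single [group_spec()] or a list of them.
#' @param seed Integer seed for all randomness (parameter draws, contour
#'   noise, covariates).
#' @return A `phantom_cohort`: a named list with one element per subject,
#'   each holding `study`, `truth` and the drawn `params`.
#' @export
generate_cohort <- function(specs, seed = 1L) {
  if (inherits(specs, "svd_group_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1L), "svd_group_spec")))
  local_seed(seed, {
    out <- list()
    for (spec in specs) {
      for (i in seq_len(spec$n_subjects)) {
        sid <- sprintf("%s_%02d", spec$group, i)
        params <- tryCatch(draw_params(spec), svdecomp_parameter_error = function(e) {
          abort(sprintf("subject %s: %s", sid, conditionMessage(e)),
                class = "svdecomp_parameter_error")
        })
        res <- tryCatch(
          generate_subject(params, subject_id = sid, group = spec$group),
          svdecomp_parameter_error = function(e) {
            abort(sprintf("subject %s: %s", sid, conditionMessage(e)),
                  class = "svdecomp_parameter_error")
          }
        )
        cov <- list()
        cm <- spec$covariates
        if (!is.null(cm$weight)) {
          cov$weight_kg <- rnorm(1L, cm$weight$mean, cm$weight$sd)
        }
        if (!is.null(cm$pcwp)) {
          long_rv <- res$truth$ventricles$longitudinal_pct[
            res$truth$ventricles$ventricle == "RV"]
          cov$pcwp_mmhg <- cm$pcwp$a + cm$pcwp$b * long_rv +
            rnorm(1L, 0, cm$pcwp$sd)
        }
        res$study$covariates <- utils::modifyList(res$study$covariates, cov)
        res$params <- params
        out[[sid]] <- res
      }
    }
    structure(out, class = "phantom_cohort")
  })
}

#' @export
print.phantom_cohort <- function(x, ...) {
  groups <- vapply(x, function(s) s$study$group, character(1L))
  cat(sprintf("<phantom_cohort> %d subjects: %s\n", length(x),
              paste(sprintf("%s (n=%d)", names(table(groups)), table(groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Ground-truth table of a cohort
#'
#' @param cohort A `phantom_cohort` from [generate_cohort()].
#' @return A tibble with one row per subject and ventricle plus the
#'   study-level truths (RF, TR, corrected RVEF, THV).
#' @export
cohort_ground_truth <- function(cohort) {
  rows <- lapply(names(cohort), function(sid) {
    tr <- cohort[[sid]]$truth
    v <- tr$ventricles
    v$subject_id <- sid
    v$group <- cohort[[sid]]$study$group
    v$rf_pct <- tr$rf_pct
    v$tr_pct <- tr$tr_pct
    v$rvef_corr_pct <- tr$rvef_corr_pct
    v$thv_ml <- tr$thv_ml
    v
  })
  dplyr::relocate(dplyr::bind_rows(rows), "subject_id", "group")
}

#' Load a cohort specification from a YAML file
#'
#' Reads a cohort design file (see
#' `system.file("extdata", "presets", "cohort_porcine_pr.yaml", package =
#' "svdecomp")`): each entry names a phantom preset (or inline calibration
#' targets), a sample size, between-subject SDs and covariate models.
#'
#' @param path YAML file.
#' @return List of [group_spec()] objects.
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y$groups, function(g) {
    params <- if (!is.null(g$preset)) {
      do.call(phantom_preset, c(list(name = g$preset), g$params_overrides))
    } else {
      do.call(phantom_params, g$params)
    }
    group_spec(
      group = g$group, n_subjects = g$n_subjects, params = params,
      sd = if (is.null(g$sd)) list() else g$sd,
      covariates = if (is.null(g$covariates)) list() else g$covariates
    )
  })
}
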