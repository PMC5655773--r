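# ggplot2 visualisations for the result classes.

#' @describeIn ventricular_volumes Volume-curve plot with ED/ES markers.
#' @param object,... `autoplot` method arguments.
#' @export
autoplot.svd_volumes <- function(object, ...) {
  curve <- object$curve
  marks <- curve[curve$frame %in% c(object$ed_frame, object$es_frame), , drop = FALSE]
  marks$phase <- ifelse(marks$frame == object$ed_frame, "ED", "ES")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time_ms, y = .data$volume_ml)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(data = marks,
                        ggplot2::aes(colour = .data$phase), size = 3) +
    ggplot2::labs(
      title = sprintf("%s volume curve", object$ventricle),
      subtitle = sprintf("EDV %.1f mL, ESV %.1f mL, SV %.1f mL, EF %.1f%%",
                         object$edv_ml, object$esv_ml, object$sv_ml,
                         100 * object$ef_fraction),
      x = "time (ms)", y = "volume (mL)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn decompose_study Bar plot of the stroke-volume components.
#' @param object,... `autoplot` method arguments.
#' @export
autoplot.svd_decomposition <- function(object, ...) {
  d <- tidy(object)
  d$component <- factor(d$component,
                        levels = c("longitudinal", "lateral", "septal", "radial"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$pct_of_sv,
                                  fill = .data$component)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      title = sprintf("%s stroke-volume decomposition", object$ventricle),
      subtitle = sprintf("summation check %.1f%% of delineated SV", object$qc_sum_pct),
      x = NULL, y = "% of stroke volume"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn build_group_table Mean +/- SEM bars per group and variable.
#' @param object Group table.
#' @param variables Subset of variables to show (default: decomposition
#'   percentages).
#' @param ... Unused.
#' @export
autoplot.svd_group_table <- function(object, variables = NULL, ...) {
  d <- tidy(object)
  if (is.null(variables)) {
    variables <- intersect(
      c("lv_longitudinal_pct", "lv_lateral_pct", "lv_septal_pct",
        "rv_longitudinal_pct", "rv_lateral_pct", "rv_septal_pct"),
      unique(d$variable)
    )
    if (!length(variables)) variables <- unique(d$variable)
  }
  d <- d[d$variable %in% variables, , drop = FALSE]
  d$group <- factor(d$group, levels = attr(object, "groups_present"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mean,
                                  fill = .data$group)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      width = 0.25
    ) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "mean +/- SEM") +
    ggplot2::theme_minimal()
}

#' @describeIn linear_fit Scatter plot with the fitted line.
#' @param object,... `autoplot` method arguments.
#' @export
autoplot.svd_linfit <- function(object, ...) {
  d <- tibble(x = object$x, y = object$y)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      subtitle = sprintf("R² = %.3f, slope p = %.3g",
                         object$r.squared, object$p.value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a pulmonary flow curve
#'
#' Shades the forward (antegrade) and retrograde lobes and annotates the
#' integrated volumes and regurgitant fraction.
#'
#' @param flow Flow-curve tibble (`time_ms`, `flow_ml_s`) or [cine_study()].
#' @return A ggplot.
#' @export
plot_flow_curve <- function(flow) {
  flow <- as_flow_curve(flow)
  ig <- integrate_flow(flow)
  rf <- regurgitant_fraction(ig$forward_ml, ig$retrograde_ml)
  ggplot2::ggplot(flow, ggplot2::aes(x = .data$time_ms, y = .data$flow_ml_s)) +
    ggplot2::geom_area(data = dplyr::mutate(flow, flow_ml_s = pmax(.data$flow_ml_s, 0)),
                       fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_area(data = dplyr::mutate(flow, flow_ml_s = pmin(.data$flow_ml_s, 0)),
                       fill = "firebrick", alpha = 0.4) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      subtitle = sprintf("forward %.1f mL, retrograde %.1f mL, RF %.1f%%",
                         ig$forward_ml, ig$retrograde_ml, rf),
      x = "time (ms)", y = "flow (mL/s)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot segmentation contours of one frame and slice
#'
#' Quick visual check of a study's contours: endocardial and epicardial
#' polygons with the RV-LV junction points.
#'
#' @param study A [cine_study()].
#' @param frame,slice Frame and slice indices.
#' @return A ggplot.
#' @export
plot_contours <- function(study, frame = 0L, slice = 0L) {
  k <- study$contours
  d <- k[k$frame == frame & k$slice == slice, , drop = FALSE]
  if (!nrow(d)) {
    abort(sprintf("no contours on frame %d slice %d", frame, slice),
          class = "svdecomp_input_error")
  }
  polys <- d[d$structure != "junctions", , drop = FALSE]
  jn <- d[d$structure == "junctions", , drop = FALSE]
  p <- ggplot2::ggplot(polys, ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                                           colour = .data$structure)) +
    ggplot2::geom_polygon(fill = NA) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("frame %d, slice %d", frame, slice),
                  x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
  if (nrow(jn)) {
    p <- p + ggplot2::geom_point(data = jn, colour = "black", shape = 4, size = 3)
  }
  p
}
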