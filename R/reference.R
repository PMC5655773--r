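#' Published group summary of the porcine PR model
#'
#' Returns the published group-level summary statistics (mean, SEM, n per
#' group) of the porcine pulmonary-regurgitation model that the phantom
#' presets emulate: volumetry, THV-indexed volumes, stroke-volume
#' contributions and regurgitant fractions for the control, PR and PPVR
#' arms. These printed summary values serve as inputs for desk-scale
#' consistency checks (radial composition, shared-wall septal conversion,
#' SV identity, summation QC) and as emulation targets for
#' [phantom_preset()].
#'
#' @return A tibble with columns `variable`, `group`, `mean`, `sem`, `n`.
#' @export
reference_group_summary <- function() {
  path <- system.file("extdata", "reference", "porcine_pr_groups.csv",
                      package = "svdecomp", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    variable = readr::col_character(),
                    group = readr::col_character(),
                    mean = readr::col_double(),
                    sem = readr::col_double(),
                    n = readr::col_integer()
                  ))
}

# convenience lookup used by scripts and tests
reference_value <- function(ref, variable, group) {
  v <- ref$mean[ref$variable == variable & ref$group == group]
  if (length(v) != 1L) {
    abort(sprintf("no unique reference value for %s / %s", variable, group),
          class = "svdecomp_input_error")
  }
  v
}
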