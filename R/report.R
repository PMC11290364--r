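#' Assemble a multi-individual summary report
#'
#' Combines per-individual [analyze_chew_trial()] results and an optional
#' workflow-precision analysis into the standard summary structure: one row
#' per individual of "mean amplitude (between-cycle CI)" for the 15 reported
#' variables (6 condylar, 3 molar, 6 symphyseal), a workflow-CI row, plus
#' across-individual ranges and the symphyseal grand means.
#'
#' @param analyses Named list of `chew_analysis` objects (names = individual
#'   ids).
#' @param precision Optional [precision_analysis()] result (or a precision
#'   tibble with `variable`, `ci`).
#' @return A `chew_report` list with `summary` (long tibble: `individual`,
#'   `variable`, `n_cycles`, `mean_amplitude`, `ci`), `table` (wide display
#'   tibble, values rounded half-up to 2 decimals), `workflow` (precision
#'   tibble or `NULL`), `aggregate` (see [aggregate_across_individuals()]),
#'   `total_cycles`.
#' @export
chew_report <- function(analyses, precision = NULL) {
  stopifnot(is.list(analyses), !is.null(names(analyses)))
  summary <- purrr::imap_dfr(analyses, ~ dplyr::mutate(tidy(.x), individual = .y,
                                                       .before = 1)) |>
    dplyr::filter(!startsWith(.data$variable, "tmj_balancing"))
  if (!is.null(precision) && !is.data.frame(precision)) precision <- precision$precision
  agg <- aggregate_across_individuals(
    summary, groups = list(
      symphyseal_rotations = paste0("symphysis_", c("rx", "ry", "rz")),
      symphyseal_translations = paste0("symphysis_", c("tx", "ty", "tz"))))
  wide <- summary |>
    dplyr::mutate(cell = sprintf("%.2f (%.2f)", round_half_up(.data$mean_amplitude, 2),
                                 round_half_up(.data$ci, 2))) |>
    dplyr::select("individual", "variable", "cell") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "cell")
  if (!is.null(precision)) {
    wf <- setNames(as.list(sprintf("%.4g", precision$ci)),
                   paste0("condyle_", precision$variable))
    wide <- dplyr::bind_rows(wide, tibble::as_tibble(c(list(individual = "workflow_ci"), wf)))
  }
  structure(list(summary = summary, table = wide, workflow = precision,
                 aggregate = agg,
                 total_cycles = sum(purrr::map_int(analyses, "n_cycles"))),
            class = "chew_report")
}

#' @export
print.chew_report <- function(x, ...) {
  cat(sprintf("<chew_report> %d individuals, %d total cycles\n",
              nrow(x$table) - !is.null(x$workflow), x$total_cycles))
  print(x$table)
  invisible(x)
}

#' Write a report to CSV and JSON
#'
#' The CSV mirrors the display table (individuals + workflow row x 15
#' variables); the JSON carries unrounded values, the per-individual
#' configuration echo and the package version.
#'
#' @param report A [chew_report()].
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @param config Optional [chew_config()] echoed into the JSON.
#' @param seed Optional seed echoed into the JSON.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL,
                         config = NULL, seed = NULL) {
  if (!is.null(csv_path)) readr::write_csv(report$table, csv_path)
  if (!is.null(json_path)) {
    payload <- list(
      version = as.character(utils::packageVersion("chewkin")),
      seed = seed,
      config = if (!is.null(config)) unclass(config),
      total_cycles = report$total_cycles,
      summary = report$summary,
      workflow_ci = report$workflow,
      ranges = report$aggregate$ranges,
      group_means = report$aggregate$group_means)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(report)
}
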