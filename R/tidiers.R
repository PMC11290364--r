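#' Tidy a chew analysis
#'
#' @param x A `chew_analysis`.
#' @param ... Unused.
#' @return Per-variable tibble: `variable`, `n_cycles`, `mean_amplitude`,
#'   `ci`, `occlusal_displacement`.
#' @export
tidy.chew_analysis <- function(x, ...) {
  x$summary
}

#' @rdname tidy.chew_analysis
#' @return `glance()`: one-row tibble with `n_cycles`, `n_frames`,
#'   `zero_frame`, `frame_rate`, `cutoff_hz`, `filter_order`,
#'   `frames_removed`, `cycles_dropped`.
#' @export
glance.chew_analysis <- function(x, ...) {
  tibble::tibble(
    n_cycles = x$n_cycles,
    n_frames = length(unique(x$poses$frame)),
    zero_frame = x$zero_frame,
    frame_rate = x$frame_rate,
    cutoff_hz = x$config$cutoff_hz %||% NA_real_,
    filter_order = x$config$filter_order,
    frames_removed = sum(x$log$frames_removed$n_missing),
    cycles_dropped = nrow(x$log$cycles_dropped))
}

#' @rdname tidy.chew_analysis
#' @export
tidy.chew_report <- function(x, ...) {
  x$summary
}

#' @rdname tidy.chew_analysis
#' @export
glance.chew_report <- function(x, ...) {
  tibble::tibble(n_individuals = length(unique(x$summary$individual)),
                 total_cycles = x$total_cycles,
                 n_variables = length(unique(x$summary$variable)))
}
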