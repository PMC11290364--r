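#' Plot a 6-DOF joint trace
#'
#' Faceted per-frame rotations (degrees) and translations (mm) of one joint.
#'
#' @param object A `jcs_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.jcs_trace <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("rx", "ry", "rz", "tx", "ty", "tz"),
                        names_to = "dof", values_to = "value") |>
    dplyr::mutate(kind = ifelse(startsWith(.data$dof, "r"),
                                "rotation (deg)", "translation (mm)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$frame, .data$value, colour = .data$dof)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~kind, ncol = 1, scales = "free_y") +
    ggplot2::labs(title = attr(object, "joint"), x = "frame", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot mean normalized cycle traces with CI bands
#'
#' Mean over cycles of each variable's 100-sample normalized trace, with the
#' pointwise t-based CI band, occlusal window shaded.
#'
#' @param object A `chew_analysis`.
#' @param variables Variables to show (default: the condylar six).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chew_analysis <- function(object,
                                   variables = paste0("condyle_",
                                                      c("rx", "ry", "rz", "tx", "ty", "tz")),
                                   ...) {
  dat <- object$cycles |>
    dplyr::filter(.data$variable %in% variables) |>
    dplyr::group_by(.data$variable, .data$sample) |>
    dplyr::summarise(mean = mean(.data$value),
                     hw = ci_halfwidth_mean(.data$value, object$config$confidence),
                     .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(.data$sample, .data$mean)) +
    ggplot2::annotate("rect", xmin = object$config$occlusal_start,
                      xmax = object$config$occlusal_end,
                      ymin = -Inf, ymax = Inf, alpha = 0.12) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$hw,
                                      ymax = .data$mean + .data$hw),
                         alpha = 0.25, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "% of chew cycle", y = "deg / mm") +
    ggplot2::theme_minimal()
}
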