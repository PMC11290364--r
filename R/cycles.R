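#' Local maxima with topographic prominence
#'
#' Finds local maxima of a trace and their prominences (height above the
#' highest of the two saddle minima separating a peak from higher terrain).
#' Plateau peaks report their earliest index. `NA` runs split the trace; peaks
#' are never detected across missing data.
#'
#' @param x Numeric trace.
#' @param min_prominence Minimum prominence to keep a peak.
#' @return Tibble with `index`, `height`, `prominence`.
#' @export
find_peaks <- function(x, min_prominence = 0) {
  res <- list()
  for (r in valid_runs(x)) {
    seg <- x[r[1]:r[2]]
    n <- length(seg)
    if (n < 3L) next
    runs <- rle(seg)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    v <- runs$values
    k <- length(v)
    for (j in seq_len(k)) {
      if (j == 1L || j == k) next
      if (v[j] > v[j - 1L] && v[j] > v[j + 1L]) {
        h <- v[j]
        left <- if (j > 1L) v[seq_len(j - 1L)] else numeric()
        right <- if (j < k) v[seq(j + 1L, k)] else numeric()
        lmin <- saddle_min(rev(left), h)
        rmin <- saddle_min(right, h)
        prom <- h - max(lmin, rmin)
        if (prom >= min_prominence) {
          res[[length(res) + 1L]] <- c(r[1] + starts[j] - 1L, h, prom)
        }
      }
    }
  }
  if (!length(res)) {
    return(tibble::tibble(index = integer(), height = numeric(), prominence = numeric()))
  }
  m <- do.call(rbind, res)
  tibble::tibble(index = as.integer(m[, 1]), height = m[, 2], prominence = m[, 3])
}

# Lowest value encountered walking away from a peak of height h until terrain
# rises above h (or the trace ends).
saddle_min <- function(vals, h) {
  lo <- h
  for (v in vals) {
    if (v >= h) break
    if (v < lo) lo <- v
  }
  lo
}

#' Segment chew cycles from a pitch trace
#'
#' Cycle boundaries are successive maxima of gape (minima of pitch toward
#' occlusion) with at least `min_prominence_deg` prominence. Cycles whose
#' pitch amplitude falls below `min_amplitude_deg` (non-chewing motion) or
#' above `max_amplitude_deg` (food-gathering cycles, which pitch more than
#' chews) are discarded, as are incomplete first/last cycles (implicitly:
#' a cycle needs a boundary on both sides).
#'
#' @param pitch_trace Per-frame pitch (degrees, positive toward closure).
#' @param min_amplitude_deg,max_amplitude_deg Amplitude gate (defaults 5, 25).
#' @param min_prominence_deg Minimum gape-peak prominence (default 3).
#' @return Tibble with `start`, `end`, `amplitude`, `kept`, `reason`
#'   (`reason` is `NA` for kept cycles).
#' @export
segment_cycles <- function(pitch_trace, min_amplitude_deg = 5,
                           max_amplitude_deg = 25, min_prominence_deg = 3) {
  peaks <- find_peaks(-pitch_trace, min_prominence = min_prominence_deg)
  if (nrow(peaks) < 2L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          amplitude = numeric(), kept = logical(),
                          reason = character()))
  }
  b <- peaks$index
  purrr::map_dfr(seq_len(length(b) - 1L), function(i) {
    seg <- pitch_trace[b[i]:b[i + 1L]]
    amp <- if (all(is.na(seg))) NA_real_ else diff(range(seg, na.rm = TRUE))
    reason <- dplyr::case_when(
      is.na(amp) ~ "all frames missing",
      amp < min_amplitude_deg ~ sprintf("amplitude %.2f below gate %.2f", amp, min_amplitude_deg),
      amp > max_amplitude_deg ~ sprintf("amplitude %.2f above gathering ceiling %.2f", amp, max_amplitude_deg),
      TRUE ~ NA_character_
    )
    tibble::tibble(start = b[i], end = b[i + 1L], amplitude = amp,
                   kept = is.na(reason), reason = reason)
  })
}

#' Time-normalize a cycle segment to a fixed number of samples
#'
#' Cubic-spline interpolation of one cycle's trace onto `n_out` evenly spaced
#' time points spanning the segment. Endpoint values are preserved. Interior
#' missing runs up to `max_gap_frac` of the segment are bridged by the spline;
#' gappier or too-short segments are an error (callers drop the cycle and log
#' the reason).
#'
#' @param x Numeric segment (one cycle of one variable); may contain interior
#'   `NA` runs.
#' @param n_out Number of output samples (default 100).
#' @param max_gap_frac Maximum interior missing run, as a fraction of the
#'   segment length (default 0.1).
#' @return Numeric vector of length `n_out`.
#' @export
normalize_cycle <- function(x, n_out = 100L, max_gap_frac = 0.1) {
  n <- length(x)
  ok <- !is.na(x)
  if (sum(ok) < 4L) {
    abort("cycle too short: fewer than 4 valid samples", class = "chewkin_error_cycle")
  }
  if (is.na(x[1]) || is.na(x[n])) {
    abort("cycle endpoints are missing", class = "chewkin_error_cycle")
  }
  gaps <- rle(ok)
  if (any(!gaps$values & gaps$lengths > max_gap_frac * n)) {
    abort(sprintf("cycle has a missing run longer than %.0f%% of the segment",
                  100 * max_gap_frac), class = "chewkin_error_cycle")
  }
  f <- splinefun(which(ok), x[ok], method = "fmm")
  f(seq(1, n, length.out = n_out))
}

#' Cycle amplitude
#'
#' Absolute magnitude of motion over one normalized cycle: `max - min`.
#'
#' @param x Numeric trace of one cycle.
#' @return Nonnegative scalar, same units as `x`.
#' @export
cycle_amplitude <- function(x) {
  diff(range(x, na.rm = TRUE))
}

#' Displacement over the occlusal window
#'
#' The occlusal phase occupies approximately the middle 40% of the chew cycle;
#' on a 100-sample normalized cycle that is samples 31-70. Reports the value
#' at window end minus value at window start (net displacement, signed) and
#' the max - min within the window.
#'
#' @param x 100-sample normalized cycle trace.
#' @param window Inclusive sample bounds (default `c(31, 70)`).
#' @return Named vector `c(displacement, range)`.
#' @export
occlusal_metrics <- function(x, window = c(31L, 70L)) {
  w <- x[window[1]:window[2]]
  c(displacement = x[window[2]] - x[window[1]],
    range = diff(range(w, na.rm = TRUE)))
}

#' Per-variable amplitude summary with between-cycle confidence intervals
#'
#' Computes, per variable, the per-cycle amplitudes, their mean, and the
#' between-cycle 95% confidence interval. The default (`ci_mode =
#' "pointwise"`) averages, over the 100 normalized time points, the pointwise
#' across-cycle t-based CI half-width of the mean trace — the time-averaged
#' width of the CI band drawn around a mean cycle trace. The alternative
#' (`ci_mode = "amplitude"`) is the t-based CI half-width of the per-cycle
#' amplitude distribution.
#'
#' @param cycles Long tibble of normalized cycles: columns `cycle`,
#'   `variable`, `sample` (1..100), `value`.
#' @param confidence Confidence level (default 0.95).
#' @param ci_mode `"pointwise"` (default) or `"amplitude"`.
#' @param occlusal_window Inclusive sample bounds of the occlusal window on
#'   the normalized cycle (default `c(31, 70)`).
#' @return Tibble with `variable`, `n_cycles`, `mean_amplitude`, `ci`
#'   (`NA` when n = 1), `occlusal_displacement` (mean over cycles of the
#'   absolute net displacement across the occlusal window).
#' @export
summarize_amplitudes <- function(cycles, confidence = 0.95,
                                 ci_mode = c("pointwise", "amplitude"),
                                 occlusal_window = c(31L, 70L)) {
  ci_mode <- match.arg(ci_mode)
  cycles <- tibble::as_tibble(cycles)
  stopifnot(all(c("cycle", "variable", "sample", "value") %in% names(cycles)))
  per_cycle <- cycles |>
    dplyr::group_by(.data$variable, .data$cycle) |>
    dplyr::summarise(amplitude = cycle_amplitude(.data$value),
                     occ_disp = occlusal_metrics(.data$value, occlusal_window)[["displacement"]],
                     .groups = "drop")
  ci_tab <- if (ci_mode == "pointwise") {
    cycles |>
      dplyr::group_by(.data$variable, .data$sample) |>
      dplyr::summarise(hw = ci_halfwidth_mean(.data$value, confidence), .groups = "drop") |>
      dplyr::group_by(.data$variable) |>
      dplyr::summarise(ci = mean(.data$hw), .groups = "drop")
  } else {
    per_cycle |>
      dplyr::group_by(.data$variable) |>
      dplyr::summarise(ci = ci_halfwidth_mean(.data$amplitude, confidence), .groups = "drop")
  }
  per_cycle |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(n_cycles = dplyr::n(),
                     mean_amplitude = mean(.data$amplitude),
                     occlusal_displacement = mean(abs(.data$occ_disp)),
                     .groups = "drop") |>
    dplyr::left_join(ci_tab, by = "variable") |>
    dplyr::mutate(ci = ifelse(.data$n_cycles < 2L, NA_real_, .data$ci)) |>
    dplyr::select("variable", "n_cycles", "mean_amplitude", "ci", "occlusal_displacement")
}

#' Aggregate amplitude summaries across individuals
#'
#' Per variable, the across-individual extrema of the individual mean
#' amplitudes (the "range"), and grand means over requested variable groups
#' (e.g. all nine symphyseal rotation entries), with half-up rounding at the
#' report precision.
#'
#' @param summaries Tibble with columns `individual`, `variable`,
#'   `mean_amplitude` (e.g. row-bound [summarize_amplitudes()] outputs).
#' @param groups Named list of character vectors of variable names to average
#'   together (grand mean over all individual x variable entries).
#' @param range_digits,mean_digits Half-up rounding for the reported range and
#'   group means (defaults 1 and 2, matching the usual report precision).
#' @return List with `ranges` (tibble: `variable`, `min`, `max`, rounded) and
#'   `group_means` (tibble: `group`, `n_entries`, `mean`, `mean_rounded`).
#' @export
aggregate_across_individuals <- function(summaries, groups = list(),
                                         range_digits = 1, mean_digits = 2) {
  summaries <- tibble::as_tibble(summaries)
  stopifnot(all(c("individual", "variable", "mean_amplitude") %in% names(summaries)))
  ranges <- summaries |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(min = round_half_up(min(.data$mean_amplitude), range_digits),
                     max = round_half_up(max(.data$mean_amplitude), range_digits),
                     .groups = "drop")
  group_means <- purrr::imap_dfr(groups, function(vars, nm) {
    vals <- summaries$mean_amplitude[summaries$variable %in% vars]
    tibble::tibble(group = nm, n_entries = length(vals), mean = mean(vals),
                   mean_rounded = round_half_up(mean(vals), mean_digits))
  })
  list(ranges = ranges, group_means = group_means)
}

#' Workflow precision from zero-motion trials
#'
#' In trials with no true relative motion (frozen cadaver heads waved through
#' the recording volume), any apparent joint motion is measurement error.
#' Pooling frames across trials, the per-variable precision is reported as the
#' half-width of the t-based 95% interval for individual frame values about
#' their mean — the scale of apparent motion attributable to the workflow
#' alone.
#'
#' @param traces A `jcs_trace` tibble or list of them (zero-motion trials).
#' @param confidence Confidence level (default 0.95).
#' @return Tibble with `variable` (`rx`..`tz`), `ci`, `n_frames`.
#' @export
workflow_precision <- function(traces, confidence = 0.95) {
  if (inherits(traces, "data.frame")) traces <- list(traces)
  if (!length(traces)) {
    abort("workflow_precision: no traces supplied", class = "chewkin_error_validation")
  }
  pooled <- purrr::map_dfr(traces, ~ tibble::as_tibble(.x)[, c("rx", "ry", "rz", "tx", "ty", "tz")]) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "variable", values_to = "value") |>
    dplyr::filter(is.finite(.data$value))
  pooled |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(ci = ci_halfwidth_values(.data$value, confidence),
                     n_frames = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(match(.data$variable, c("rx", "ry", "rz", "tx", "ty", "tz")))
}
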