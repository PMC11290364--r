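#' Analysis configuration
#'
#' All tunables of the analysis pipeline. Unknown keys are rejected. Every
#' analysis output embeds the configuration used.
#'
#' @param cutoff_hz Low-pass Butterworth cutoff for marker coordinates
#'   (default 20 Hz; `NULL` disables filtering).
#' @param filter_order Butterworth order per pass (default 2).
#' @param min_amplitude_deg,max_amplitude_deg Pitch-amplitude cycle gate
#'   (defaults 5 and 25 degrees; the ceiling excludes food-gathering cycles,
#'   which pitch more than chews).
#' @param min_prominence_deg Gape-peak prominence for cycle boundaries
#'   (default 3 degrees).
#' @param occlusal_start,occlusal_end Occlusal window on the 100-sample
#'   normalized cycle (defaults 31 and 70: the middle 40%).
#' @param ci_mode Between-cycle CI estimator: `"pointwise"` (default) or
#'   `"amplitude"` (see [summarize_amplitudes()]).
#' @param zero_frame Optional explicit zero frame; `NA` (default) selects the
#'   frame of peak closure of the representative chew (the kept cycle whose
#'   pitch amplitude is closest to the median).
#' @param working_side `"right"` (default) or `"left"`: the TMJ reported as
#'   the condylar joint.
#' @param max_gap_frac Maximum interior missing run inside a cycle, as a
#'   fraction of the cycle length (default 0.1).
#' @param n_samples Samples per normalized cycle (default 100).
#' @param confidence Confidence level for CIs (default 0.95).
#' @return A `chew_config` list.
#' @export
chew_config <- function(cutoff_hz = 20, filter_order = 2,
                        min_amplitude_deg = 5, max_amplitude_deg = 25,
                        min_prominence_deg = 3,
                        occlusal_start = 31L, occlusal_end = 70L,
                        ci_mode = c("pointwise", "amplitude"),
                        zero_frame = NA_integer_,
                        working_side = c("right", "left"),
                        max_gap_frac = 0.1, n_samples = 100L,
                        confidence = 0.95) {
  structure(list(cutoff_hz = cutoff_hz, filter_order = filter_order,
                 min_amplitude_deg = min_amplitude_deg,
                 max_amplitude_deg = max_amplitude_deg,
                 min_prominence_deg = min_prominence_deg,
                 occlusal_start = as.integer(occlusal_start),
                 occlusal_end = as.integer(occlusal_end),
                 ci_mode = match.arg(ci_mode),
                 zero_frame = zero_frame,
                 working_side = match.arg(working_side),
                 max_gap_frac = max_gap_frac,
                 n_samples = as.integer(n_samples),
                 confidence = confidence),
            class = "chew_config")
}

get_landmark <- function(landmarks, body, name) {
  r <- landmarks[landmarks$body == body & landmarks$landmark == name, ]
  if (nrow(r) != 1L) {
    abort(sprintf("landmark '%s' on body '%s' not found (or duplicated)", name, body),
          class = "chewkin_error_validation")
  }
  c(r$x, r$y, r$z)
}

pose_at <- function(poses, body, frame) {
  r <- poses[poses$body == body & poses$frame == frame, ]
  if (nrow(r) != 1L || !isTRUE(r$ok)) return(NULL)
  r$transform[[1]]
}

# Cranial ACS from landmarks, with hints derived from landmarks and the
# condyle centroids mapped through the poses at a reference frame.
cranial_acs_from_landmarks <- function(landmarks, poses, ref_frame,
                                       origin_landmark = "maxillary_occlusal_center") {
  cusps <- landmarks[landmarks$body == "cranium" &
                       grepl("^cusp_", landmarks$landmark), ]
  if (nrow(cusps) < 3L) {
    abort("need >= 3 cusp_* landmarks on the cranium", class = "chewkin_error_validation")
  }
  long_axis <- get_landmark(landmarks, "cranium", "cranial_axis_anterior") -
    get_landmark(landmarks, "cranium", "cranial_axis_posterior")
  pc <- pose_at(poses, "cranium", ref_frame)
  pr <- pose_at(poses, "right_hemimandible", ref_frame)
  pl <- pose_at(poses, "left_hemimandible", ref_frame)
  if (is.null(pc) || is.null(pr) || is.null(pl)) {
    abort(sprintf("no valid poses at reference frame %d", ref_frame),
          class = "chewkin_error_validation")
  }
  cr_w <- rt_apply(pr, get_landmark(landmarks, "right_hemimandible", "condyle_centroid_right"))
  cl_w <- rt_apply(pl, get_landmark(landmarks, "left_hemimandible", "condyle_centroid_left"))
  right_hint <- as.numeric(t(pc$R) %*% (cr_w - cl_w))
  build_cranial_acs(as.matrix(cusps[, c("x", "y", "z")]), long_axis, right_hint,
                    get_landmark(landmarks, "cranium", origin_landmark))
}

# The four joint definitions (both TMJs, symphysis) cloned at `zero_frame`.
build_jcs_definitions <- function(cranial_acs, landmarks, poses, zero_frame) {
  pc <- pose_at(poses, "cranium", zero_frame)
  pr <- pose_at(poses, "right_hemimandible", zero_frame)
  pl <- pose_at(poses, "left_hemimandible", zero_frame)
  if (is.null(pc) || is.null(pr) || is.null(pl)) {
    abort(sprintf("cannot clone ACS: missing pose at zero frame %d", zero_frame),
          class = "chewkin_error_validation")
  }
  acs_r <- clone_acs_to_body(cranial_acs, pc, pr, "right_hemimandible",
                             get_landmark(landmarks, "right_hemimandible", "condyle_centroid_right"))
  acs_l <- clone_acs_to_body(cranial_acs, pc, pl, "left_hemimandible",
                             get_landmark(landmarks, "left_hemimandible", "condyle_centroid_left"))
  sym_l <- clone_acs_to_body(cranial_acs, pc, pl, "left_hemimandible",
                             get_landmark(landmarks, "left_hemimandible", "symphysis_centroid"))
  sym_r <- clone_acs_to_body(cranial_acs, pc, pr, "right_hemimandible",
                             get_landmark(landmarks, "right_hemimandible", "symphysis_centroid"))
  list(
    tmj_right = jcs_definition("tmj_right", "cranium", "right_hemimandible",
                               cranial_acs, acs_r, zero_frame),
    tmj_left = jcs_definition("tmj_left", "cranium", "left_hemimandible",
                              cranial_acs, acs_l, zero_frame),
    symphysis = jcs_definition("symphysis", "left_hemimandible", "right_hemimandible",
                               sym_l, sym_r, zero_frame)
  )
}

#' Analyze one chewing trial
#'
#' The full pipeline: low-pass filtering of marker coordinates, per-frame pose
#' estimation, anatomical and joint coordinate-system construction with a
#' data-driven zero pose (peak closure of the representative chew), 6-DOF
#' traces at both TMJs and the symphysis plus the molar-locator translation
#' trace, chew-cycle segmentation and 100-sample time normalization, and
#' per-variable amplitude summaries with between-cycle CIs.
#'
#' @param markers Long marker trajectory tibble (`frame`, `body`, `marker`,
#'   `x`, `y`, `z`) or a `chew_sim` object (its components are then used).
#' @param constellations Named list of [marker_constellation()] objects.
#' @param landmarks Landmark tibble (see [read_landmarks()]).
#' @param frame_rate Hz.
#' @param config A [chew_config()].
#' @return A `chew_analysis` object: list with `traces` (named list of
#'   `jcs_trace`/`locator_trace`), `segments`, `cycles` (long normalized
#'   tibble), `summary` (per-variable amplitude summary), `zero_frame`,
#'   `n_cycles`, `poses`, `log`, `config`, `frame_rate`.
#' @export
#' @examples
#' sim <- simulate_chew_trial(chew_model_params("A", n_cycles = 3))
#' fit <- analyze_chew_trial(sim)
#' tidy(fit)
analyze_chew_trial <- function(markers, constellations = NULL, landmarks = NULL,
                               frame_rate = NULL, config = chew_config()) {
  if (inherits(markers, "chew_sim")) {
    constellations <- markers$constellations
    landmarks <- markers$landmarks
    frame_rate <- markers$frame_rate
    markers <- markers$markers
  }
  stopifnot(!is.null(constellations), !is.null(landmarks), !is.null(frame_rate))
  filtered <- filter_trajectories(markers, frame_rate, config$cutoff_hz,
                                  config$filter_order)
  poses <- estimate_poses(filtered, constellations)
  frames_removed <- poses |>
    dplyr::group_by(.data$body) |>
    dplyr::summarise(n_missing = sum(!.data$ok), .groups = "drop")

  ok_all <- poses |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(ok = all(.data$ok), .groups = "drop")
  ref_frame <- ok_all$frame[which(ok_all$ok)[1]]
  if (is.na(ref_frame)) {
    abort("no frame has valid poses for all bodies", class = "chewkin_error_validation")
  }

  working <- paste0("tmj_", config$working_side)
  cr_acs <- cranial_acs_from_landmarks(landmarks, poses, ref_frame)

  # Provisional pitch trace (zero at the first valid frame) for segmentation
  # and zero-frame selection.
  prov <- build_jcs_definitions(cr_acs, landmarks, poses, ref_frame)
  prov_rz <- fill_by_frame(compute_joint_trace(poses, prov[[working]]))$rz
  segs <- segment_cycles(prov_rz, config$min_amplitude_deg,
                         config$max_amplitude_deg, config$min_prominence_deg)
  kept <- segs[segs$kept, ]

  zero_frame <- config$zero_frame
  if (is.null(zero_frame) || is.na(zero_frame)) {
    if (!nrow(kept)) {
      abort("no qualifying chew cycles; supply config$zero_frame to analyze anyway",
            class = "chewkin_error_validation")
    }
    rep_i <- which.min(abs(kept$amplitude - median(kept$amplitude)))
    zero_frame <- find_zero_frame(prov_rz, c(kept$start[rep_i], kept$end[rep_i]))
  }

  defs <- build_jcs_definitions(cr_acs, landmarks, poses, zero_frame)
  molar_ref <- anatomical_cs("cranium",
                             get_landmark(landmarks, "cranium", "maxillary_occlusal_center"),
                             cr_acs$axes)
  traces <- list(
    tmj_right = compute_joint_trace(poses, defs$tmj_right),
    tmj_left = compute_joint_trace(poses, defs$tmj_left),
    symphysis = compute_joint_trace(poses, defs$symphysis),
    molar = compute_locator_trace(poses, "right_hemimandible",
                                  get_landmark(landmarks, "right_hemimandible", "molar2_locator"),
                                  molar_ref, zero_frame)
  )

  # Final segmentation on the zero-referenced working-side pitch.
  segs <- segment_cycles(fill_by_frame(traces[[working]])$rz,
                         config$min_amplitude_deg, config$max_amplitude_deg,
                         config$min_prominence_deg)
  kept <- segs[segs$kept, ]

  var_tab <- trace_variables(traces, working)
  cyc_res <- normalize_cycles(var_tab, kept, config)

  summary <- if (nrow(cyc_res$cycles)) {
    summarize_amplitudes(cyc_res$cycles, config$confidence, config$ci_mode,
                         c(config$occlusal_start, config$occlusal_end))
  } else {
    tibble::tibble(variable = character(), n_cycles = integer(),
                   mean_amplitude = numeric(), ci = numeric(),
                   occlusal_displacement = numeric())
  }

  structure(list(traces = traces, segments = segs, cycles = cyc_res$cycles,
                 summary = summary, zero_frame = zero_frame,
                 n_cycles = length(unique(cyc_res$cycles$cycle)),
                 poses = poses,
                 log = list(frames_removed = frames_removed,
                            cycles_dropped = dplyr::bind_rows(
                              segs[!segs$kept, c("start", "end", "reason")],
                              cyc_res$dropped)),
                 config = config, frame_rate = frame_rate),
            class = "chew_analysis")
}

# A trace tibble indexed by frame with NA rows where frames are absent,
# so segment indices equal frame numbers.
fill_by_frame <- function(trace) {
  all_frames <- tibble::tibble(frame = seq_len(max(trace$frame)))
  dplyr::left_join(all_frames, tibble::as_tibble(trace), by = "frame")
}

# Long per-frame table of the reported variables.
trace_variables <- function(traces, working = "tmj_right") {
  grab <- function(trace, joint, dofs) {
    fill_by_frame(trace)[, c("frame", dofs)] |>
      tidyr::pivot_longer(-"frame", names_to = "dof", values_to = "value") |>
      dplyr::mutate(variable = paste0(joint, "_", .data$dof)) |>
      dplyr::select("frame", "variable", "value")
  }
  six <- c("rx", "ry", "rz", "tx", "ty", "tz")
  dplyr::bind_rows(
    grab(traces[[working]], "condyle", six),
    grab(traces$molar, "molar", c("tx", "ty", "tz")),
    grab(traces$symphysis, "symphysis", six),
    grab(traces[[setdiff(c("tmj_right", "tmj_left"), working)]], "tmj_balancing", six)
  )
}

# Normalize every kept cycle for every variable; drop a cycle entirely if any
# variable fails (too short / too gappy), logging the reason.
normalize_cycles <- function(var_tab, kept, config) {
  dropped <- list()
  rows <- list()
  wide <- tidyr::pivot_wider(var_tab, names_from = "variable", values_from = "value") |>
    dplyr::arrange(.data$frame)
  vars <- setdiff(names(wide), "frame")
  for (i in seq_len(nrow(kept))) {
    seg <- wide[wide$frame >= kept$start[i] & wide$frame <= kept$end[i], ]
    res <- tryCatch({
      purrr::map(vars, ~ normalize_cycle(seg[[.x]], config$n_samples, config$max_gap_frac))
    }, chewkin_error_cycle = function(e) e)
    if (inherits(res, "error")) {
      dropped[[length(dropped) + 1L]] <- tibble::tibble(
        start = kept$start[i], end = kept$end[i], reason = conditionMessage(res))
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      cycle = i,
      variable = rep(vars, each = config$n_samples),
      sample = rep(seq_len(config$n_samples), length(vars)),
      value = unlist(res))
  }
  list(cycles = dplyr::bind_rows(rows), dropped = dplyr::bind_rows(dropped))
}

#' @export
print.chew_analysis <- function(x, ...) {
  cat(sprintf("<chew_analysis> %d cycles (zero frame %d, %g Hz)\n",
              x$n_cycles, x$zero_frame, x$frame_rate))
  print(x$summary, n = 15)
  invisible(x)
}

#' Workflow-precision analysis of zero-motion trials
#'
#' Runs the same filtering / pose / coordinate-system pipeline on one or more
#' zero-motion (cadaver) trials — the zero pose defaults to the first valid
#' frame since there are no chew cycles — and pools the working-side TMJ
#' traces into a [workflow_precision()] report.
#'
#' @param sims A `chew_sim` (from [simulate_cadaver_trial()]) or list of them;
#'   alternatively a list of prepared `jcs_trace` tables via
#'   [workflow_precision()] directly.
#' @param config A [chew_config()].
#' @return List with `precision` (tibble `variable`, `ci`, `n_frames`) and
#'   `traces` (the pooled working-side traces).
#' @export
precision_analysis <- function(sims, config = chew_config()) {
  if (inherits(sims, "chew_sim")) sims <- list(sims)
  working <- paste0("tmj_", config$working_side)
  traces <- purrr::map(sims, function(sim) {
    filtered <- filter_trajectories(sim$markers, sim$frame_rate,
                                    config$cutoff_hz, config$filter_order)
    poses <- estimate_poses(filtered, sim$constellations)
    ok_all <- poses |>
      dplyr::group_by(.data$frame) |>
      dplyr::summarise(ok = all(.data$ok), .groups = "drop")
    ref_frame <- ok_all$frame[which(ok_all$ok)[1]]
    cr_acs <- cranial_acs_from_landmarks(sim$landmarks, poses, ref_frame)
    defs <- build_jcs_definitions(cr_acs, sim$landmarks, poses, ref_frame)
    compute_joint_trace(poses, defs[[working]])
  })
  list(precision = workflow_precision(traces, config$confidence), traces = traces)
}
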