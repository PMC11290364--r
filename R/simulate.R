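#' Synthetic proal-chewing model parameters
#'
#' Parameters of the synthetic trial generator. Per-individual defaults take
#' their 15 amplitudes and cycle counts from [reference_amplitudes()]
#' ("A"-like is the default scenario); every value can be overridden. The
#' condylar amplitudes are injected on the right (working-side) TMJ, the
#' symphyseal amplitudes at the symphysis; the left hemimandible follows from
#' both. Molar-locator motion is emergent from geometry and has analytic
#' ground truth, not an injected amplitude.
#'
#' @param individual `"A"`, `"B"` or `"C"` to pull that individual's
#'   amplitudes and cycle count (B also uses the 3-marker right hemimandible
#'   variant).
#' @param ... Overrides for any parameter listed below.
#' @return A `chew_model_params` list with fields:
#'   `n_cycles`; `cycle_rate` (Hz, default 5); `frame_rate` (Hz, default 250);
#'   `pitch_amplitude_deg`, `yaw_amplitude_deg`, `roll_amplitude_deg`;
#'   `condylar_tx_mm`, `condylar_ty_mm`, `condylar_tz_mm`;
#'   `occlusal_tx_fraction` (fraction of the anterior excursion inside the
#'   occlusal window, default 0.55); `occlusal_fraction` (default 0.40);
#'   `occlusal_dip` (closure-bump depth inside occlusion, fraction of pitch
#'   amplitude, default 0.02); symphyseal `symphysis_rx/ry/rz_deg`,
#'   `symphysis_tx/ty/tz_mm`; `head_motion_mm`, `head_motion_deg`,
#'   `head_motion_hz`; `marker_noise_sigma` (mm, default 0.05);
#'   `missing_rate`; `constellation_spread` (RMS marker distance from the
#'   constellation centroid, mm, default 3.5); `right_markers` (4 or 3);
#'   `cadaver_seconds`; `seed`.
#' @export
#' @examples
#' chew_model_params("A", marker_noise_sigma = 0)
chew_model_params <- function(individual = "A", ...) {
  ref <- reference_amplitudes()
  a <- setNames(ref$amplitude[ref$individual == individual],
                ref$variable[ref$individual == individual])
  if (!length(a)) abort("unknown individual", class = "chewkin_error_config")
  p <- list(
    individual = individual,
    n_cycles = unique(ref$n_cycles[ref$individual == individual]),
    cycle_rate = 5,
    frame_rate = 250,
    pitch_amplitude_deg = a[["condyle_rz"]],
    yaw_amplitude_deg = a[["condyle_ry"]],
    roll_amplitude_deg = a[["condyle_rx"]],
    condylar_tx_mm = a[["condyle_tx"]],
    condylar_ty_mm = a[["condyle_ty"]],
    condylar_tz_mm = a[["condyle_tz"]],
    occlusal_tx_fraction = 0.55,
    occlusal_fraction = 0.40,
    occlusal_dip = 0.02,
    symphysis_rx_deg = a[["symphysis_rx"]],
    symphysis_ry_deg = a[["symphysis_ry"]],
    symphysis_rz_deg = a[["symphysis_rz"]],
    symphysis_tx_mm = a[["symphysis_tx"]],
    symphysis_ty_mm = a[["symphysis_ty"]],
    symphysis_tz_mm = a[["symphysis_tz"]],
    head_motion_mm = 2,
    head_motion_deg = 2,
    head_motion_hz = 0.7,
    marker_noise_sigma = 0.05,
    missing_rate = 0,
    constellation_spread = 3.5,
    right_markers = if (individual == "B") 3L else 4L,
    cadaver_seconds = 4,
    seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) {
    abort(paste("unknown parameter(s):", paste(bad, collapse = ", ")),
          class = "chewkin_error_config")
  }
  p[names(dots)] <- dots
  stopifnot(p$occlusal_fraction > 0, p$occlusal_fraction < 1,
            p$cycle_rate < p$frame_rate / 4)
  structure(p, class = "chew_model_params")
}

# ---- scene geometry ---------------------------------------------------------

# Unit tetrahedron directions (RMS radius 1) with a fixed asymmetric warp so
# no constellation has accidental symmetry.
tetra_dirs <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  v + matrix(c(0.11, -0.05, 0.04,
               -0.08, 0.10, -0.03,
               0.05, 0.02, 0.12,
               -0.04, -0.09, -0.07), 4, 3, byrow = TRUE)
}

body_constellation <- function(body, center, spread, n_markers = 4L) {
  dirs <- tetra_dirs()
  if (n_markers == 3L) dirs <- dirs[1:3, , drop = FALSE]
  dirs <- dirs / sqrt(mean(rowSums(dirs^2)))   # RMS radius 1
  coords <- sweep(dirs * spread, 2, center, "+")
  marker_constellation(body, tibble::tibble(
    marker = paste0("m", seq_len(nrow(coords))),
    x = coords[, 1], y = coords[, 2], z = coords[, 3]))
}

#' Build the synthetic scene geometry
#'
#' Deterministic placement (given the parameters) of the three bones'
#' reference marker constellations and anatomical landmarks in a canonical
#' occluded posture, in which every bone's model frame coincides with the
#' world frame: X anterior, Y superior, Z to the animal's right, upper
#' tooth-row cusps exactly on the y = 0 occlusal plane.
#'
#' @param params A [chew_model_params()] object.
#' @return A `chew_scene` list with `constellations` (named list),
#'   `landmarks` (tibble `body`, `landmark`, `x`, `y`, `z`) and `cusp_points`
#'   (matrix).
#' @export
build_scene <- function(params) {
  spread <- params$constellation_spread
  cons <- list(
    cranium = body_constellation("cranium", c(-8, 6, 0), spread),
    left_hemimandible = body_constellation("left_hemimandible", c(-2, -4, -7), spread),
    right_hemimandible = body_constellation("right_hemimandible", c(-2, -4, 7),
                                            spread, params$right_markers)
  )
  cusp_x <- c(-6.5, -3.8, -1.2, 1.4, -6.1, -3.5, -0.9, 1.7)
  cusp_z <- c(3.4, 3.6, 3.5, 3.3, -3.5, -3.4, -3.6, -3.2)
  cusps <- cbind(x = cusp_x, y = 0, z = cusp_z)
  lm <- tibble::tribble(
    ~body, ~landmark, ~x, ~y, ~z,
    "cranium", "maxillary_occlusal_center", 0, 0, 3.5,
    "cranium", "cranial_axis_anterior", 12, 1, 0,
    "cranium", "cranial_axis_posterior", -14, 1, 0,
    "right_hemimandible", "condyle_centroid_right", -12, 1.5, 8,
    "left_hemimandible", "condyle_centroid_left", -12, 1.5, -8,
    "left_hemimandible", "symphysis_centroid", 10, -2, 0,
    "right_hemimandible", "symphysis_centroid", 10, -2, 0,
    "right_hemimandible", "molar2_locator", 0, -0.4, 3.5
  )
  cusp_lm <- tibble::tibble(body = "cranium",
                            landmark = paste0("cusp_", seq_len(nrow(cusps))),
                            x = cusps[, 1], y = cusps[, 2], z = cusps[, 3])
  structure(list(constellations = cons,
                 landmarks = dplyr::bind_rows(cusp_lm, lm),
                 cusp_points = cusps),
            class = "chew_scene")
}

# ---- waveforms --------------------------------------------------------------

# Raised-cosine smoothstep on [0, 1].
rcstep <- function(u) 0.5 * (1 - cos(pi * pmin(1, pmax(0, u))))

# Closure profile c(phi) in [0, 1]: 0 at maximum gape (phi = 0), 1 at peak
# closure (phi = 0.5, unique because of the shallow occlusal closure bump).
closure_profile <- function(phi, occlusal_fraction = 0.4, dip = 0.02) {
  a <- (1 - occlusal_fraction) / 2
  b <- 1 - a
  out <- numeric(length(phi))
  lo <- phi < a
  mid <- phi >= a & phi <= b
  hi <- phi > b
  out[lo] <- (1 - dip) * rcstep(phi[lo] / a)
  out[mid] <- 1 - dip + dip * 0.5 * (1 + cos(2 * pi * (phi[mid] - 0.5) / (b - a)))
  out[hi] <- (1 - dip) * rcstep((1 - phi[hi]) / a)
  out
}

# Anterior-translation profile: monotone anterior ramp concentrating
# `frac` of the excursion inside the occlusal window, return during opening.
# Centered so the value at phi = 0.5 is zero; total max - min equals `amp`.
proal_tx_profile <- function(phi, amp, frac, occlusal_fraction = 0.4) {
  a <- (1 - occlusal_fraction) / 2
  b <- 1 - a
  p <- numeric(length(phi))
  lo <- phi < a
  mid <- phi >= a & phi <= b
  hi <- phi > b
  p[lo] <- (1 - frac) * amp * rcstep(phi[lo] / a)
  p[mid] <- (1 - frac) * amp + frac * amp * rcstep((phi[mid] - a) / (b - a))
  p[hi] <- amp * (1 - rcstep((phi[hi] - b) / a))
  p - (1 - frac) * amp - frac * amp * 0.5
}

# Sinusoid with max - min = amp, vanishing at phi = 0.5 (the zero posture).
dof_sin <- function(phi, amp, harmonic = 1) {
  (amp / 2) * sin(2 * pi * harmonic * (phi - 0.5))
}

# The 12 injected DOF waveforms at cycle phases `phi` (condylar DOFs on the
# right TMJ; symphyseal DOFs). All are exactly zero at phi = 0.5.
chew_waveforms <- function(phi, params) {
  p <- params
  tibble::tibble(
    condyle_rx = dof_sin(phi, p$roll_amplitude_deg, 2),
    condyle_ry = dof_sin(phi, p$yaw_amplitude_deg, 1),
    condyle_rz = p$pitch_amplitude_deg *
      (closure_profile(phi, p$occlusal_fraction, p$occlusal_dip) - 1),
    condyle_tx = proal_tx_profile(phi, p$condylar_tx_mm, p$occlusal_tx_fraction,
                                  p$occlusal_fraction),
    condyle_ty = dof_sin(phi, p$condylar_ty_mm, 1),
    condyle_tz = dof_sin(phi, p$condylar_tz_mm, 2),
    symphysis_rx = dof_sin(phi, p$symphysis_rx_deg, 1),
    symphysis_ry = dof_sin(phi, p$symphysis_ry_deg, 2),
    symphysis_rz = dof_sin(phi, p$symphysis_rz_deg, 1),
    symphysis_tx = dof_sin(phi, p$symphysis_tx_mm, 2),
    symphysis_ty = dof_sin(phi, p$symphysis_ty_mm, 1),
    symphysis_tz = dof_sin(phi, p$symphysis_tz_mm, 1)
  )
}

# Slow whole-scene rigid "head" motion at time t (seconds).
head_motion_transform <- function(t, amp_mm, amp_deg, hz) {
  if (amp_mm == 0 && amp_deg == 0) return(rt_identity())
  R <- rot_z(amp_deg * sin(2 * pi * hz * t)) %*%
    rot_y(amp_deg * sin(2 * pi * hz * 1.31 * t + 0.7)) %*%
    rot_x(amp_deg * sin(2 * pi * hz * 0.77 * t + 1.9))
  tr <- amp_mm * c(sin(2 * pi * hz * t + 0.3),
                   sin(2 * pi * hz * 1.17 * t + 2.1),
                   sin(2 * pi * hz * 0.89 * t + 4.0))
  rigid_transform(R, tr)
}

# ---- kinematics -------------------------------------------------------------

#' Generate ground-truth poses and joint traces
#'
#' Builds per-frame ground-truth poses for the cranium and both hemimandibles
#' from the injected chew waveforms, plus the analytic ground-truth joint and
#' locator traces. The trial spans `n_cycles + 1` gape cycles starting at
#' mid-occlusion, so exactly `n_cycles` complete cycles lie between interior
#' gape maxima.
#'
#' @param params [chew_model_params()].
#' @param scene [build_scene()] output.
#' @return List with `frames`, `time`, `phase`, `poses` (tibble: `frame`,
#'   `body`, `transform`, `ok`), `truth` (long tibble: `frame`, `variable`,
#'   `value` for the 15 reported variables plus the left TMJ), `zero_frames`
#'   (frames at exact peak closure), `boundary_frames` (gape maxima).
#' @export
generate_kinematics <- function(params, scene) {
  p <- params
  fpc <- p$frame_rate / p$cycle_rate
  if (abs(fpc - round(fpc)) > 1e-9) {
    warn("frame_rate is not an integer multiple of cycle_rate; peak-closure frames will not be sampled exactly")
  }
  n_frames <- as.integer(round((p$n_cycles + 1) * fpc)) + 1L
  frames <- seq_len(n_frames)
  t <- (frames - 1) / p$frame_rate
  phi_abs <- 0.5 + p$cycle_rate * t
  phi <- phi_abs %% 1
  w <- chew_waveforms(phi, p)

  lmk <- scene$landmarks
  lm <- function(body, name) {
    r <- lmk[lmk$body == body & lmk$landmark == name, ]
    c(r$x, r$y, r$z)
  }
  c_r <- lm("right_hemimandible", "condyle_centroid_right")
  c_l <- lm("left_hemimandible", "condyle_centroid_left")
  s <- lm("right_hemimandible", "symphysis_centroid")
  locator <- lm("right_hemimandible", "molar2_locator")
  o_ref <- lm("cranium", "maxillary_occlusal_center")

  poses <- vector("list", 3L * n_frames)
  truth_rows <- vector("list", n_frames)
  bodies <- c("cranium", "right_hemimandible", "left_hemimandible")
  for (i in frames) {
    H <- head_motion_transform(t[i], p$head_motion_mm, p$head_motion_deg, p$head_motion_hz)
    R_r <- rot_z(w$condyle_rz[i]) %*% rot_y(w$condyle_ry[i]) %*% rot_x(w$condyle_rx[i])
    u_r <- c(w$condyle_tx[i], w$condyle_ty[i], w$condyle_tz[i])
    V_r <- rigid_transform(R_r, c_r + u_r - as.numeric(R_r %*% c_r))
    R_sym <- rot_z(w$symphysis_rz[i]) %*% rot_y(w$symphysis_ry[i]) %*% rot_x(w$symphysis_rx[i])
    u_sym <- c(w$symphysis_tx[i], w$symphysis_ty[i], w$symphysis_tz[i])
    R_l <- R_r %*% t(R_sym)
    V_l <- rigid_transform(R_l, rt_apply(V_r, s) - as.numeric(R_l %*% u_sym) -
                             as.numeric(R_l %*% s))
    poses[[i]] <- list(H, rt_compose(H, V_r), rt_compose(H, V_l))

    mol <- rt_apply(V_r, locator) - locator       # cranial axes are identity here
    tmj_l <- jcs_decompose(rigid_transform(R_l, rt_apply(V_l, c_l) - c_l))
    truth_rows[[i]] <- c(mol, tmj_l[1:6])
  }
  pose_tab <- tibble::tibble(
    frame = rep(frames, each = 3L),
    body = rep(bodies, n_frames),
    transform = purrr::flatten(poses),
    rms = 0, n_used = NA_integer_, ok = TRUE)

  tm <- do.call(rbind, truth_rows)
  truth <- dplyr::bind_cols(
    tibble::tibble(frame = frames),
    w,
    tibble::tibble(molar_tx = tm[, 1], molar_ty = tm[, 2], molar_tz = tm[, 3],
                   tmj_left_rx = tm[, 4], tmj_left_ry = tm[, 5], tmj_left_rz = tm[, 6],
                   tmj_left_tx = tm[, 7], tmj_left_ty = tm[, 8], tmj_left_tz = tm[, 9])) |>
    tidyr::pivot_longer(-"frame", names_to = "variable", values_to = "value")

  k <- seq_len(p$n_cycles + 1L)
  list(frames = frames, time = t, phase = phi, poses = pose_tab, truth = truth,
       zero_frames = as.integer(1 + k * fpc)[seq_len(p$n_cycles)],
       boundary_frames = as.integer(1 + (k - 0.5) * fpc))
}

# ---- marker rendering -------------------------------------------------------

#' Render noisy marker trajectories from poses
#'
#' Maps each bone's reference markers through its per-frame pose, adds i.i.d.
#' isotropic Gaussian noise per coordinate, and drops marker-frames to missing
#' with probability `missing_rate`. Fully deterministic given `params$seed`.
#'
#' @param scene [build_scene()] output.
#' @param poses Pose tibble (`frame`, `body`, `transform`).
#' @param params [chew_model_params()].
#' @return Long trajectory tibble: `frame`, `body`, `marker`, `x`, `y`, `z`.
#' @export
render_markers <- function(scene, poses, params) {
  sigma <- params$marker_noise_sigma
  miss <- params$missing_rate
  out <- poses |>
    dplyr::mutate(pts = purrr::map2(.data$body, .data$transform, function(b, tr) {
      con <- scene$constellations[[b]]
      coords <- rt_apply(tr, as.matrix(con$markers[, c("x", "y", "z")]))
      tibble::tibble(marker = con$markers$marker,
                     x = coords[, 1], y = coords[, 2], z = coords[, 3])
    })) |>
    dplyr::select("frame", "body", "pts") |>
    tidyr::unnest("pts") |>
    dplyr::arrange(.data$body, .data$marker, .data$frame)
  n <- nrow(out)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(params$seed)
  noise <- matrix(stats::rnorm(3L * n, sd = 1), n, 3)
  drop <- stats::runif(n) < miss
  out$x <- out$x + sigma * noise[, 1]
  out$y <- out$y + sigma * noise[, 2]
  out$z <- out$z + sigma * noise[, 3]
  out$x[drop] <- NA_real_; out$y[drop] <- NA_real_; out$z[drop] <- NA_real_
  dplyr::arrange(out, .data$frame, .data$body, .data$marker)
}

#' Simulate a complete chewing trial
#'
#' Runs [build_scene()], [generate_kinematics()] and [render_markers()] and
#' bundles the result: noisy marker trajectories, reference constellations,
#' landmarks, ground-truth poses and traces, and the parameters used.
#'
#' @param params [chew_model_params()].
#' @return A `chew_sim` list with elements `markers`, `constellations`,
#'   `landmarks`, `scene`, `kinematics`, `params`, `frame_rate`.
#' @export
#' @examples
#' sim <- simulate_chew_trial(chew_model_params("A", n_cycles = 3))
#' dplyr::count(sim$markers, body)
simulate_chew_trial <- function(params = chew_model_params()) {
  scene <- build_scene(params)
  kin <- generate_kinematics(params, scene)
  markers <- render_markers(scene, kin$poses, params)
  structure(list(markers = markers, constellations = scene$constellations,
                 landmarks = scene$landmarks, scene = scene, kinematics = kin,
                 params = params, frame_rate = params$frame_rate),
            class = "chew_sim")
}

#' Simulate a zero-motion (cadaver) precision trial
#'
#' All three bodies share one rigid whole-scene "waving" motion, so true
#' relative joint motion is identically zero; marker noise and missingness are
#' applied as in [simulate_chew_trial()]. Used to quantify workflow precision.
#'
#' @param params [chew_model_params()]; `head_motion_*` set the waving
#'   amplitude and `cadaver_seconds` the duration.
#' @return A `chew_sim` list (no chew kinematics; `kinematics$poses` holds the
#'   shared waving poses).
#' @export
simulate_cadaver_trial <- function(params = chew_model_params(head_motion_mm = 10,
                                                              head_motion_deg = 10)) {
  scene <- build_scene(params)
  n_frames <- as.integer(round(params$cadaver_seconds * params$frame_rate))
  frames <- seq_len(n_frames)
  t <- (frames - 1) / params$frame_rate
  bodies <- c("cranium", "right_hemimandible", "left_hemimandible")
  pose_tab <- tibble::tibble(
    frame = rep(frames, each = 3L),
    body = rep(bodies, n_frames),
    transform = rep(purrr::map(t, head_motion_transform,
                               amp_mm = params$head_motion_mm,
                               amp_deg = params$head_motion_deg,
                               hz = params$head_motion_hz), each = 3L),
    rms = 0, n_used = NA_integer_, ok = TRUE)
  markers <- render_markers(scene, pose_tab, params)
  structure(list(markers = markers, constellations = scene$constellations,
                 landmarks = scene$landmarks, scene = scene,
                 kinematics = list(poses = pose_tab, frames = frames, time = t),
                 params = params, frame_rate = params$frame_rate),
            class = "chew_sim")
}
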