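#' Joint coordinate system definitions
#'
#' A JCS pairs a fixed (proximal) and a mobile (distal) body, each carrying an
#' ACS, with a zero frame at which all six degrees of freedom are zero by
#' definition. Following the joint-coordinate-system convention, the Z
#' (lateral) rotation axis is fixed to the proximal bone, the X (anterior)
#' axis to the distal bone, and Y floats orthogonal to both — an intrinsic
#' Z-Y'-X'' factorization of the zero-referenced relative rotation.
#'
#' @param name Joint name (`"tmj_right"`, `"tmj_left"`, `"symphysis"`, ...).
#' @param fixed_body,mobile_body Body identifiers.
#' @param fixed_acs,mobile_acs [anatomical_cs()] objects on those bodies, with
#'   origins at the joint landmark (condyle centroid, symphysis centroid).
#' @param zero_frame Frame index defining the zero pose.
#' @return A `jcs_definition` object.
#' @export
jcs_definition <- function(name, fixed_body, mobile_body, fixed_acs, mobile_acs,
                           zero_frame) {
  stopifnot(inherits(fixed_acs, "anatomical_cs"), inherits(mobile_acs, "anatomical_cs"))
  structure(list(name = name, fixed_body = fixed_body, mobile_body = mobile_body,
                 fixed_acs = fixed_acs, mobile_acs = mobile_acs,
                 zero_frame = as.integer(zero_frame)),
            class = "jcs_definition")
}

#' Decompose a zero-referenced relative pose into 6 degrees of freedom
#'
#' Factorizes the relative rotation as `R = Rz(Rz_deg) Ry(Ry_deg) Rx(Rx_deg)`
#' (Z fixed to the proximal body, X to the distal body, Y floating) and
#' reports the translation components directly. Angles are reported in
#' degrees within (-180, 180]; a `gimbal` flag is raised when |Ry| comes
#' within 0.5 degrees of 90 (values are still returned).
#'
#' @param relative A [rigid_transform()]: the zero-referenced relative pose of
#'   the mobile ACS in fixed-ACS coordinates (identity at the zero frame).
#' @return Named numeric vector `c(rx, ry, rz, tx, ty, tz)` (degrees, mm) with
#'   attribute `gimbal` (logical).
#' @export
#' @examples
#' p <- jcs_compose(1, 2, 10, 0.5, 0, 0)
#' jcs_decompose(p)
jcs_decompose <- function(relative) {
  stopifnot(inherits(relative, "rigid_transform"))
  R <- relative$R
  sy <- -R[3, 1]
  ry <- asin(pmin(1, pmax(-1, sy)))
  if (abs(abs(sy) - 1) < 1e-12) {
    # Exact gimbal lock: rz and rx are not separable; attribute all to rz.
    rz <- atan2(-R[1, 2], R[2, 2])
    rx <- 0
  } else {
    rz <- atan2(R[2, 1], R[1, 1])
    rx <- atan2(R[3, 2], R[3, 3])
  }
  out <- c(rx = wrap_deg(rad2deg(rx)),
           ry = wrap_deg(rad2deg(ry)),
           rz = wrap_deg(rad2deg(rz)),
           tx = relative$t[1], ty = relative$t[2], tz = relative$t[3])
  attr(out, "gimbal") <- abs(abs(out[["ry"]]) - 90) < 0.5
  out
}

#' @rdname jcs_decompose
#' @param rx,ry,rz Roll, yaw, pitch in degrees (applied in the hierarchy
#'   order: pitch about fixed Z, then floating yaw, then roll about mobile X).
#' @param tx,ty,tz Translation components, mm, along the fixed ACS axes.
#' @export
jcs_compose <- function(rx = 0, ry = 0, rz = 0, tx = 0, ty = 0, tz = 0) {
  rigid_transform(rot_z(rz) %*% rot_y(ry) %*% rot_x(rx), c(tx, ty, tz))
}

# World-frame ACS orientation and origin for one body at one frame.
acs_world <- function(pose, acs) {
  list(Q = pose$R %*% acs$axes, p = rt_apply(pose, acs$origin))
}

# Align two bodies' pose sequences on a shared frame clock.
pose_pair <- function(poses, body_a, body_b) {
  pa <- poses[poses$body == body_a, ]
  pb <- poses[poses$body == body_b, ]
  frames <- sort(intersect(pa$frame, pb$frame))
  if (!setequal(pa$frame, pb$frame)) {
    warn("bodies do not share an identical frame clock; using the intersection")
  }
  list(frames = frames,
       a = pa$transform[match(frames, pa$frame)],
       a_ok = pa$ok[match(frames, pa$frame)],
       b = pb$transform[match(frames, pb$frame)],
       b_ok = pb$ok[match(frames, pb$frame)])
}

#' Per-frame 6-DOF joint trace
#'
#' Computes the zero-referenced relative pose of the mobile ACS with respect
#' to the fixed ACS at every frame and decomposes it with [jcs_decompose()].
#' Rotations are JCS angles (degrees); translations are the components of the
#' mobile ACS origin's displacement from its zero-frame position, expressed in
#' the fixed body's ACS axes (mm). Frames where either body's pose is missing
#' yield missing rows.
#'
#' @param poses Pose tibble from [estimate_poses()] (columns `frame`, `body`,
#'   `transform`, `ok`).
#' @param definition A [jcs_definition()].
#' @return A tibble of class `jcs_trace` with columns `frame`, `rx`, `ry`,
#'   `rz`, `tx`, `ty`, `tz`, `gimbal`, `missing`; attributes `joint`,
#'   `zero_frame`, `fixed_body`, `mobile_body`.
#' @export
compute_joint_trace <- function(poses, definition) {
  stopifnot(inherits(definition, "jcs_definition"))
  pp <- pose_pair(poses, definition$fixed_body, definition$mobile_body)
  zi <- match(definition$zero_frame, pp$frames)
  if (is.na(zi) || !isTRUE(pp$a_ok[zi]) || !isTRUE(pp$b_ok[zi])) {
    abort(sprintf("joint '%s': no valid pose at zero frame %d",
                  definition$name, definition$zero_frame),
          class = "chewkin_error_validation")
  }
  f0 <- acs_world(pp$a[[zi]], definition$fixed_acs)
  m0 <- acs_world(pp$b[[zi]], definition$mobile_acs)
  C0 <- crossprod(f0$Q, m0$Q)
  d0 <- as.numeric(crossprod(f0$Q, m0$p - f0$p))

  n <- length(pp$frames)
  out <- matrix(NA_real_, n, 6)
  gimbal <- rep(NA, n)
  for (i in seq_len(n)) {
    if (!isTRUE(pp$a_ok[i]) || !isTRUE(pp$b_ok[i])) next
    f <- acs_world(pp$a[[i]], definition$fixed_acs)
    m <- acs_world(pp$b[[i]], definition$mobile_acs)
    Rrel <- crossprod(f$Q, m$Q) %*% t(C0)
    d <- as.numeric(crossprod(f$Q, m$p - f$p)) - d0
    dec <- jcs_decompose(structure(list(R = Rrel, t = d), class = "rigid_transform"))
    out[i, ] <- dec
    gimbal[i] <- attr(dec, "gimbal")
  }
  trace <- tibble::tibble(frame = pp$frames,
                          rx = out[, 1], ry = out[, 2], rz = out[, 3],
                          tx = out[, 4], ty = out[, 5], tz = out[, 6],
                          gimbal = gimbal,
                          missing = is.na(out[, 1]))
  structure(trace, class = c("jcs_trace", class(trace)),
            joint = definition$name, zero_frame = definition$zero_frame,
            fixed_body = definition$fixed_body, mobile_body = definition$mobile_body)
}

#' Translation trace of a locator point
#'
#' Tracks a point fixed to a mobile body (e.g. a digital locator on the lower
#' second molar's occlusal surface), expressed in a reference ACS on the fixed
#' body (the cranial ACS translated to a supplied origin), minus its
#' zero-frame value.
#'
#' @param poses Pose tibble from [estimate_poses()].
#' @param mobile_body Body the locator is attached to.
#' @param locator_point 3-vector, mm, in the mobile body's model frame.
#' @param reference An [anatomical_cs()] on the fixed body (origin already
#'   translated to the measurement point, e.g. the maxillary occlusal center).
#' @param zero_frame Frame at which the trace is zero.
#' @return Tibble of class `locator_trace` with `frame`, `tx`, `ty`, `tz`,
#'   `missing`.
#' @export
compute_locator_trace <- function(poses, mobile_body, locator_point, reference,
                                  zero_frame) {
  stopifnot(inherits(reference, "anatomical_cs"))
  locator_point <- check_point3(locator_point, "locator_point")
  pp <- pose_pair(poses, reference$body, mobile_body)
  zi <- match(as.integer(zero_frame), pp$frames)
  if (is.na(zi) || !isTRUE(pp$a_ok[zi]) || !isTRUE(pp$b_ok[zi])) {
    abort(sprintf("locator: no valid pose at zero frame %d", zero_frame),
          class = "chewkin_error_validation")
  }
  loc_in_ref <- function(i) {
    f <- acs_world(pp$a[[i]], reference)
    xw <- rt_apply(pp$b[[i]], locator_point)
    as.numeric(crossprod(f$Q, xw - f$p))
  }
  u0 <- loc_in_ref(zi)
  n <- length(pp$frames)
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (!isTRUE(pp$a_ok[i]) || !isTRUE(pp$b_ok[i])) next
    out[i, ] <- loc_in_ref(i) - u0
  }
  trace <- tibble::tibble(frame = pp$frames,
                          tx = out[, 1], ty = out[, 2], tz = out[, 3],
                          missing = is.na(out[, 1]))
  structure(trace, class = c("locator_trace", class(trace)),
            zero_frame = as.integer(zero_frame), mobile_body = mobile_body)
}
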