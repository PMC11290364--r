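#' Anatomical coordinate systems
#'
#' An anatomical coordinate system (ACS) is an origin plus a right-handed
#' orthonormal axis triad rigidly attached to a bone, expressed in that bone's
#' model frame. The package convention is X anterior, Y superior, Z to the
#' animal's right (columns of `axes`, with `X x Y = Z`).
#'
#' @param body Body the ACS is attached to.
#' @param origin 3-vector, mm, in the bone model frame.
#' @param axes 3x3 matrix whose columns are the X, Y, Z unit vectors.
#' @return An `anatomical_cs` object.
#' @export
anatomical_cs <- function(body, origin, axes) {
  origin <- check_point3(origin, "origin")
  axes <- unname(as.matrix(axes))
  if (max(abs(crossprod(axes) - diag(3))) > 1e-9 || det(axes) < 0) {
    abort("ACS axes must be orthonormal and right-handed",
          class = "chewkin_error_validation")
  }
  structure(list(body = body, origin = origin, axes = axes), class = "anatomical_cs")
}

#' @export
print.anatomical_cs <- function(x, ...) {
  cat(sprintf("<anatomical_cs> body '%s'\norigin (mm): %s\naxes (columns X,Y,Z):\n",
              x$body, paste(format(x$origin, digits = 6), collapse = " ")))
  print(round(x$axes, 6))
  invisible(x)
}

#' Build the cranial ACS from occlusal-plane landmarks
#'
#' Fits the occlusal plane to the cusp points of the upper tooth row, then
#' sets X to the unit projection of the cranial long-axis hint into that
#' plane, Z in-plane orthogonal to X with its sign chosen toward the right
#' hint, and Y = Z x X (superior positive, checked against the plane normal
#' orientation implied by the hints).
#'
#' @param cusp_points n x 3 matrix of upper tooth-row cusp points (>= 3,
#'   non-collinear), bone model frame, mm.
#' @param long_axis_hint 3-vector pointing anteriorly along the cranial long
#'   axis (need not be in-plane; must not be parallel to the plane normal).
#' @param right_hint 3-vector with a positive component toward the animal's
#'   right.
#' @param origin ACS origin landmark (mm, model frame).
#' @param body Body name (default `"cranium"`).
#' @return An [anatomical_cs()].
#' @export
build_cranial_acs <- function(cusp_points, long_axis_hint, right_hint, origin,
                              body = "cranium") {
  long_axis_hint <- check_point3(long_axis_hint, "long_axis_hint")
  right_hint <- check_point3(right_hint, "right_hint")
  # Normal oriented so that (anterior, right, normal) hints form Y = Z x X:
  up_hint <- cross3(right_hint, long_axis_hint)
  if (sqrt(sum(up_hint^2)) < 1e-12) {
    abort("long_axis_hint and right_hint are parallel", class = "chewkin_error_degenerate")
  }
  plane <- fit_plane(cusp_points, up_hint)
  n <- plane$normal
  x_in <- long_axis_hint - sum(long_axis_hint * n) * n
  if (sqrt(sum(x_in^2)) < 1e-9 * sqrt(sum(long_axis_hint^2))) {
    abort("long_axis_hint is parallel to the occlusal plane normal",
          class = "chewkin_error_degenerate")
  }
  X <- unit(x_in)
  Z <- cross3(X, n)        # in-plane, orthogonal to X
  if (sum(Z * right_hint) < 0) Z <- -Z
  Z <- unit(Z)
  Y <- cross3(Z, X)
  anatomical_cs(body, origin, cbind(X, Y, Z))
}

#' Clone an ACS orientation onto another body
#'
#' Re-expresses a source ACS's world-frame orientation, at a chosen reference
#' frame, in a target body's model frame — e.g. giving the mandible an ACS
#' with identical alignment to the cranial ACS at the zero posture. The origin
#' is a supplied landmark on the target body (condyle centroid, symphysis
#' centroid).
#'
#' @param source An [anatomical_cs()] on the source body.
#' @param source_pose,target_pose [rigid_transform()] poses (model frame to
#'   world) of source and target bodies at the reference frame; `NULL` poses
#'   (missing frames) are an error.
#' @param target_body Name of the target body.
#' @param origin Landmark origin (mm) in the target body's model frame.
#' @return An [anatomical_cs()] on the target body.
#' @export
clone_acs_to_body <- function(source, source_pose, target_pose, target_body, origin) {
  stopifnot(inherits(source, "anatomical_cs"))
  if (is.null(source_pose) || is.null(target_pose)) {
    abort("clone_acs_to_body: pose missing at the reference frame",
          class = "chewkin_error_validation")
  }
  world_axes <- source_pose$R %*% source$axes
  anatomical_cs(target_body, origin, t(target_pose$R) %*% world_axes)
}

#' Frame of peak jaw closure within a cycle
#'
#' Returns the frame of maximum pitch toward occlusion (minimum gape) within
#' a designated cycle — the frame used as the joint zero pose ("centric
#' occlusion of a representative chew"). Ties are broken by the earliest
#' frame.
#'
#' @param pitch_trace Per-frame pitch angle (degrees, positive toward
#'   closure); may contain `NA`.
#' @param cycle Integer frame interval `c(start, end)` (default: whole trace).
#' @return Frame index (into `pitch_trace`).
#' @export
find_zero_frame <- function(pitch_trace, cycle = c(1L, length(pitch_trace))) {
  idx <- seq(max(1L, cycle[1]), min(length(pitch_trace), cycle[2]))
  seg <- pitch_trace[idx]
  if (all(is.na(seg))) {
    abort("find_zero_frame: pitch trace is all missing in the cycle",
          class = "chewkin_error_validation")
  }
  idx[which.max(seg)]   # which.max returns the first maximum
}
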