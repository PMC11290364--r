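#' Rigid transforms
#'
#' A rigid transform is a proper rotation plus a translation, mapping
#' coordinates in one frame into another: `y = R x + t`. It is the currency of
#' all pose arithmetic in the package: bone poses, anatomical coordinate
#' system changes of basis, and joint zero poses are all rigid transforms.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1 (checked to
#'   1e-9 on construction).
#' @param translation Numeric 3-vector, millimeters.
#' @return An object of class `rigid_transform` with fields `R` and `t`.
#' @export
#' @examples
#' T1 <- rigid_transform(rot_z(30), c(1, 2, 3))
#' rt_apply(T1, c(1, 0, 0))
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- check_point3(translation, "translation")
  if (!all(dim(rotation) == c(3L, 3L)) || !all(is.finite(rotation))) {
    abort("rotation must be a finite 3x3 matrix", class = "chewkin_error_validation")
  }
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-9 || abs(det(rotation) - 1) > 1e-9) {
    abort("rotation must be orthonormal with determinant +1 (tolerance 1e-9)",
          class = "chewkin_error_validation")
  }
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n")
  print(round(x$R, 6))
  cat("translation (mm):", format(x$t, digits = 6), "\n")
  invisible(x)
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform()

#' Compose and invert rigid transforms
#'
#' `rt_compose(a, b)` is the transform applying `b` first, then `a`
#' (`(a o b)(x) = a(b(x))`); `rt_invert(a)` is the inverse transform.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  structure(list(R = a$R %*% b$R, t = as.numeric(a$R %*% b$t) + a$t),
            class = "rigid_transform")
}

#' @rdname rt_compose
#' @export
rt_invert <- function(a) {
  stopifnot(inherits(a, "rigid_transform"))
  Rt <- t(a$R)
  structure(list(R = Rt, t = as.numeric(-Rt %*% a$t)), class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param a A `rigid_transform`.
#' @param x A 3-vector or an n x 3 matrix of row points.
#' @return Same shape as `x`.
#' @export
rt_apply <- function(a, x) {
  stopifnot(inherits(a, "rigid_transform"))
  if (is.matrix(x)) {
    sweep(x %*% t(a$R), 2, a$t, "+")
  } else {
    as.numeric(a$R %*% x) + a$t
  }
}

#' Elementary rotation matrices
#'
#' Right-handed rotations about the coordinate axes, angle in degrees.
#' With the package convention (X anterior, Y superior, Z lateral-right),
#' positive `rot_z` pitches the jaw toward closure, positive `rot_y` yaws the
#' mandible toward the animal's left, positive `rot_x` rolls the right side
#' superiorly.
#'
#' @param deg Angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rot_x <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(1, 0, 0,
           0, cos(a), -sin(a),
           0, sin(a), cos(a)), 3, 3, byrow = TRUE)
}

#' @rdname rot_x
#' @export
rot_y <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), 0, sin(a),
           0, 1, 0,
           -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}

#' @rdname rot_x
#' @export
rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), -sin(a), 0,
           sin(a), cos(a), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# Rotation angle (degrees) of the relative rotation between two transforms;
# used in tests and diagnostics.
rt_rotation_angle <- function(a, b = rt_identity()) {
  Rrel <- t(b$R) %*% a$R
  cosang <- (sum(diag(Rrel)) - 1) / 2
  rad2deg(acos(pmin(1, pmax(-1, cosang))))
}
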