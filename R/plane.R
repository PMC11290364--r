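#' Total-least-squares plane fit
#'
#' Fits a plane to 3D points by minimizing perpendicular distances (the
#' smallest principal component of the centered coordinates). Used to fit the
#' occlusal plane to the cusps of the upper tooth row when building the
#' cranial anatomical coordinate system.
#'
#' @param points An n x 3 matrix or data frame of point coordinates (mm),
#'   n >= 3, non-collinear.
#' @param orientation_hint 3-vector; the returned normal is flipped if needed
#'   so that `dot(normal, orientation_hint) > 0`.
#' @param collinear_tol Smallest allowed second singular value (mm) of the
#'   centered coordinate matrix before the points are declared collinear.
#' @return A list of class `chewkin_plane` with `origin` (centroid of the
#'   points) and `normal` (unit 3-vector).
#' @export
#' @examples
#' pts <- cbind(runif(10), runif(10), 0)
#' fit_plane(pts, c(0, 0, 1))$normal
fit_plane <- function(points, orientation_hint, collinear_tol = 1e-8) {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 3L || nrow(pts) < 3L || !all(is.finite(pts))) {
    abort("fit_plane needs >= 3 finite 3D points",
          class = "chewkin_error_degenerate")
  }
  hint <- check_point3(orientation_hint, "orientation_hint")
  centroid <- colMeans(pts)
  centered <- sweep(pts, 2, centroid)
  sv <- svd(centered)
  if (sv$d[2] <= collinear_tol * max(sv$d[1], 1)) {
    abort("fit_plane: points are collinear", class = "chewkin_error_degenerate")
  }
  normal <- sv$v[, 3]
  if (sum(normal * hint) < 0) normal <- -normal
  if (sum(normal * hint) == 0) {
    abort("orientation_hint is perpendicular to the fitted normal; sign is undefined",
          class = "chewkin_error_degenerate")
  }
  structure(list(origin = unname(centroid), normal = unname(unit(normal))),
            class = "chewkin_plane")
}
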