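#' Marker constellations
#'
#' A marker constellation is the set of reference marker coordinates of one
#' bone, expressed in that bone's model frame (from CT in a typical study).
#' At least 3 non-collinear markers are required to define a pose.
#'
#' @param body Body name (e.g. `"cranium"`).
#' @param markers Tibble/data frame with columns `marker`, `x`, `y`, `z` (mm).
#' @param collinear_tol Minimum second singular value (mm) of the centered
#'   marker coordinates (default 0.1 mm).
#' @return A `marker_constellation` object.
#' @export
marker_constellation <- function(body, markers, collinear_tol = 0.1) {
  markers <- tibble::as_tibble(markers)
  stopifnot(all(c("marker", "x", "y", "z") %in% names(markers)))
  coords <- as.matrix(markers[, c("x", "y", "z")])
  if (nrow(coords) < 3L || !all(is.finite(coords))) {
    abort(sprintf("body '%s': a constellation needs >= 3 finite markers", body),
          class = "chewkin_error_degenerate")
  }
  sv <- svd(sweep(coords, 2, colMeans(coords)))$d
  if (sv[2] <= collinear_tol) {
    abort(sprintf("body '%s': markers are collinear (second singular value %.3g mm <= %.3g mm)",
                  body, sv[2], collinear_tol),
          class = "chewkin_error_degenerate")
  }
  structure(list(body = body, markers = markers, collinear_tol = collinear_tol),
            class = "marker_constellation")
}

#' @export
print.marker_constellation <- function(x, ...) {
  cat(sprintf("<marker_constellation> body '%s', %d markers\n", x$body, nrow(x$markers)))
  print(x$markers)
  invisible(x)
}

#' Least-squares rigid pose from observed markers
#'
#' Estimates the rigid transform mapping a bone's reference marker coordinates
#' onto their observed 3D positions (orthogonal Procrustes / Kabsch solution,
#' reflections excluded), the root-mean-square residual over the markers used,
#' and the number of markers used. Markers observed as missing (`NA`) are
#' excluded, never imputed; fewer than 3 usable markers makes the pose
#' undefined for that frame.
#'
#' @param reference A [marker_constellation()] (or a data frame with `marker`,
#'   `x`, `y`, `z`).
#' @param observed Data frame with columns `marker`, `x`, `y`, `z`; missing
#'   observations as `NA`. Rows are matched to the reference by `marker`.
#' @return A list with `transform` (a [rigid_transform()], or `NULL` when the
#'   pose is undefined), `rms` (mm), `n_used`, and `ok` (logical).
#' @export
estimate_pose <- function(reference, observed) {
  if (inherits(reference, "marker_constellation")) {
    ref_tab <- reference$markers
    tol <- reference$collinear_tol
    body <- reference$body
  } else {
    ref_tab <- tibble::as_tibble(reference)
    tol <- 0.1
    body <- "body"
  }
  obs <- tibble::as_tibble(observed)
  stopifnot(all(c("marker", "x", "y", "z") %in% names(obs)))
  obs <- obs[match(ref_tab$marker, obs$marker), , drop = FALSE]
  usable <- stats::complete.cases(obs[, c("x", "y", "z")])
  n_used <- sum(usable)
  if (n_used < 3L) {
    return(list(transform = NULL, rms = NA_real_, n_used = n_used, ok = FALSE))
  }
  X <- as.matrix(ref_tab[usable, c("x", "y", "z")])
  Y <- as.matrix(obs[usable, c("x", "y", "z")])
  svX <- svd(sweep(X, 2, colMeans(X)))$d
  if (svX[2] <= tol) {
    abort(sprintf("body '%s': usable marker subset is collinear", body),
          class = "chewkin_error_degenerate")
  }
  xbar <- colMeans(X); ybar <- colMeans(Y)
  H <- crossprod(sweep(X, 2, xbar), sweep(Y, 2, ybar))
  sv <- svd(H)
  d <- det(sv$v %*% t(sv$u))
  R <- sv$v %*% diag(c(1, 1, sign(d))) %*% t(sv$u)
  tr <- ybar - as.numeric(R %*% xbar)
  resid <- sweep(X %*% t(R), 2, tr, "+") - Y
  list(transform = rigid_transform(R, tr),
       rms = sqrt(mean(rowSums(resid^2))),
       n_used = n_used,
       ok = TRUE)
}

#' Per-frame pose estimation for every body in a trajectory table
#'
#' Runs [estimate_pose()] for each body and frame of a marker trajectory
#' table. Frames with fewer than 3 usable markers for a body yield a missing
#' pose for that body; missingness propagates through all downstream traces.
#'
#' @param trajectories Long marker trajectory tibble with columns
#'   `frame`, `body`, `marker`, `x`, `y`, `z` (see [read_marker_csv()]).
#' @param constellations Named list of [marker_constellation()] objects (or a
#'   single tibble with a `body` column).
#' @return A tibble with columns `frame`, `body`, `transform` (list column of
#'   [rigid_transform()] or `NULL`), `rms`, `n_used`, `ok`.
#' @export
estimate_poses <- function(trajectories, constellations) {
  traj <- tibble::as_tibble(trajectories)
  stopifnot(all(c("frame", "body", "marker", "x", "y", "z") %in% names(traj)))
  if (is.data.frame(constellations)) {
    constellations <- constellations |>
      dplyr::group_by(.data$body) |>
      dplyr::group_split() |>
      purrr::map(~ marker_constellation(.x$body[1], .x[, c("marker", "x", "y", "z")]))
    names(constellations) <- purrr::map_chr(constellations, "body")
  }
  traj |>
    tidyr::nest(obs = c("marker", "x", "y", "z")) |>
    dplyr::mutate(fit = purrr::map2(.data$body, .data$obs, function(b, o) {
      con <- constellations[[b]]
      if (is.null(con)) {
        abort(sprintf("no reference constellation for body '%s'", b),
              class = "chewkin_error_validation")
      }
      estimate_pose(con, o)
    })) |>
    dplyr::mutate(transform = purrr::map(.data$fit, "transform"),
                  rms = purrr::map_dbl(.data$fit, "rms"),
                  n_used = purrr::map_int(.data$fit, "n_used"),
                  ok = purrr::map_lgl(.data$fit, "ok")) |>
    dplyr::select("frame", "body", "transform", "rms", "n_used", "ok") |>
    dplyr::arrange(.data$body, .data$frame)
}
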