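# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used for
#' printed summary tables), unlike [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.125, 2.5, -2.5), 2)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

is_point3 <- function(p) {
  is.numeric(p) && length(p) == 3L && all(is.finite(p))
}

check_point3 <- function(p, what = "point") {
  if (!is_point3(p)) {
    abort(sprintf("%s must be a finite numeric 3-vector", what),
          class = "chewkin_error_validation")
  }
  unname(as.numeric(p))
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) {
    abort("cannot normalize a zero vector", class = "chewkin_error_degenerate")
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap angles (degrees) into (-180, 180].
wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

# t-based half-widths used by the cycle statistics and precision modules.
ci_halfwidth_mean <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  qt(1 - (1 - level) / 2, df = n - 1) * sd(x) / sqrt(n)
}

ci_halfwidth_values <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  qt(1 - (1 - level) / 2, df = n - 1) * sd(x)
}
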