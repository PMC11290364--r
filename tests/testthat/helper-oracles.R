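# Shared helpers: random geometry and independent oracles used across tests.

rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_rotation <- function(max_deg = 180) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  rodrigues(ax * stats::runif(1, 0, max_deg * pi / 180))
}

random_transform <- function(max_deg = 180, max_mm = 10) {
  rigid_transform(random_rotation(max_deg), stats::runif(3, -max_mm, max_mm))
}

# Brute-force nonlinear least-squares pose oracle: minimizes the sum of
# squared marker distances over a rotation-vector + translation
# parameterization, multi-started from identity and the three 180-degree
# flips to avoid local minima. Independent of the closed-form estimator.
brute_force_pose <- function(X, Y) {
  obj <- function(p) {
    R <- rodrigues(p[1:3])
    sum((sweep(X %*% t(R), 2, p[4:6], "+") - Y)^2)
  }
  t0 <- colMeans(Y) - colMeans(X)
  starts <- list(c(0, 0, 0), c(pi, 0, 0), c(0, pi, 0), c(0, 0, pi))
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(c(s, t0), obj, method = "BFGS",
                        control = list(reltol = 1e-16, maxit = 2000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # Gauss-Newton polish of the best start down to machine precision
  R_best <- rodrigues(best$par[1:3])
  t_best <- best$par[4:6]
  for (k in 1:30) {
    P <- sweep(X %*% t(R_best), 2, t_best, "+")
    E <- P - Y                      # residuals, n x 3
    J <- NULL; r <- NULL
    for (i in seq_len(nrow(X))) {
      p <- P[i, ] - t_best
      Sk <- matrix(c(0, -p[3], p[2], p[3], 0, -p[1], -p[2], p[1], 0),
                   3, 3, byrow = TRUE)
      J <- rbind(J, cbind(-Sk, diag(3)))
      r <- c(r, E[i, ])
    }
    step <- solve(crossprod(J), crossprod(J, -r))
    R_best <- rodrigues(step[1:3]) %*% R_best
    t_best <- t_best + step[4:6]
    if (sqrt(sum(step^2)) < 1e-14) break
  }
  P <- sweep(X %*% t(R_best), 2, t_best, "+")
  list(R = R_best, t = t_best, rms = sqrt(sum((P - Y)^2) / nrow(X)))
}

# Small-noise analytic covariance oracle for Kabsch rotation error:
# rotation-vector covariance = sigma^2 * M^-1 with M the second-moment matrix
# of the centered marker coordinates.
rotation_noise_sd <- function(coords, sigma) {
  r <- sweep(coords, 2, colMeans(coords))
  M <- diag(3) * sum(r^2) - crossprod(r)
  sqrt(diag(sigma^2 * solve(M)))
}

# Compact scenario used by many tests: small, fast, deterministic.
tiny_params <- function(...) {
  chew_model_params("A", n_cycles = 3, marker_noise_sigma = 0,
                    head_motion_mm = 0, head_motion_deg = 0, ...)
}

no_filter <- function(...) chew_config(cutoff_hz = NULL, ...)
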