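test_that("scene construction is deterministic and satisfies its invariants", {
  p <- chew_model_params("A")
  s1 <- build_scene(p)
  s2 <- build_scene(p)
  expect_identical(s1$landmarks, s2$landmarks)
  for (con in s1$constellations) {
    coords <- as.matrix(con$markers[, c("x", "y", "z")])
    sv <- svd(sweep(coords, 2, colMeans(coords)))$d
    expect_gt(sv[2], 0.1)
  }
  # cusp points sit exactly on the occlusal plane with a superior normal
  pl <- fit_plane(s1$cusp_points, c(0, 1, 0))
  expect_lt(max(abs(pl$normal - c(0, 1, 0))), 1e-9)
  # rat-B variant exercises the 3-marker constellation
  sb <- build_scene(chew_model_params("B"))
  expect_equal(nrow(sb$constellations$right_hemimandible$markers), 3L)
})

test_that("zero amplitudes freeze the specimen", {
  p <- tiny_params(pitch_amplitude_deg = 0, yaw_amplitude_deg = 0,
                   roll_amplitude_deg = 0, condylar_tx_mm = 0,
                   condylar_ty_mm = 0, condylar_tz_mm = 0,
                   symphysis_rx_deg = 0, symphysis_ry_deg = 0,
                   symphysis_rz_deg = 0, symphysis_tx_mm = 0,
                   symphysis_ty_mm = 0, symphysis_tz_mm = 0)
  kin <- generate_kinematics(p, build_scene(p))
  first <- kin$poses$transform[1:3]
  for (i in seq_len(nrow(kin$poses))) {
    ref <- first[[match(kin$poses$body[i], kin$poses$body[1:3])]]
    expect_lt(max(abs(kin$poses$transform[[i]]$R - ref$R)), 1e-12)
    expect_lt(max(abs(kin$poses$transform[[i]]$t - ref$t)), 1e-12)
  }
})

test_that("analytic ground-truth amplitudes equal the injected parameters", {
  p <- tiny_params(n_cycles = 5)
  kin <- generate_kinematics(p, build_scene(p))
  truth <- kin$truth |>
    dplyr::group_by(variable) |>
    dplyr::summarise(amp = diff(range(value)))
  amp_of <- function(v) truth$amp[truth$variable == v]
  # pitch and anterior-translation extremes sit exactly on the frame grid
  expect_equal(amp_of("condyle_rz"), p$pitch_amplitude_deg, tolerance = 1e-12)
  expect_equal(amp_of("condyle_tx"), p$condylar_tx_mm, tolerance = 1e-12)
  # sinusoidal DOF extremes fall between samples: discrete amplitude is
  # A * cos(pi * harmonic / frames_per_cycle)
  fpc <- p$frame_rate / p$cycle_rate
  expect_equal(amp_of("condyle_ry"), p$yaw_amplitude_deg * cos(pi / fpc),
               tolerance = 1e-9)
  # (for h = 2 with fpc = 50 the nearest-sample offset halves, so the
  # attenuation factor is the same cos(pi/fpc))
  expect_equal(amp_of("condyle_rx"), p$roll_amplitude_deg * cos(pi / fpc),
               tolerance = 1e-9)
  expect_equal(amp_of("symphysis_rz"), p$symphysis_rz_deg * cos(pi / fpc),
               tolerance = 1e-9)
  expect_equal(amp_of("symphysis_ty"), p$symphysis_ty_mm * cos(pi / fpc),
               tolerance = 1e-9)
  # all injected waveforms vanish at the peak-closure frames
  at_zero <- kin$truth |>
    dplyr::filter(frame %in% kin$zero_frames,
                  !startsWith(variable, "molar"), !startsWith(variable, "tmj_left"))
  expect_lt(max(abs(at_zero$value)), 1e-9)
})

test_that("noiseless rendering lets pose estimation recover ground truth", {
  p <- tiny_params(n_cycles = 2)
  sim <- simulate_chew_trial(p)
  poses <- estimate_poses(sim$markers, sim$constellations)
  for (f in c(1L, 37L, 80L)) {
    for (b in c("cranium", "right_hemimandible", "left_hemimandible")) {
      est <- poses$transform[[which(poses$frame == f & poses$body == b)]]
      tru <- sim$kinematics$poses$transform[[
        which(sim$kinematics$poses$frame == f & sim$kinematics$poses$body == b)]]
      expect_lt(max(abs(est$R - tru$R)), 1e-9)
      expect_lt(max(abs(est$t - tru$t)), 1e-9)
    }
  }
})

test_that("pose rms residuals are consistent with the noise model", {
  # residual dof argument: E[sum resid^2] = sigma^2 (3n - 6) for n markers
  sigma <- 0.05
  p <- chew_model_params("A", n_cycles = 2, marker_noise_sigma = sigma, seed = 5)
  sim <- simulate_chew_trial(p)
  poses <- estimate_poses(sim$markers, sim$constellations)
  rms_mean <- mean(poses$rms[poses$body == "cranium"])
  expected <- sigma * sqrt((3 * 4 - 6) / 4)
  expect_lt(abs(rms_mean - expected) / expected, 0.2)
})

test_that("the same seed reproduces a trial bit-for-bit, different seeds do not", {
  p <- chew_model_params("A", n_cycles = 2, missing_rate = 0.02)
  s1 <- simulate_chew_trial(p)
  s2 <- simulate_chew_trial(p)
  expect_identical(s1$markers, s2$markers)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_marker_csv(s1$markers, f1, p$frame_rate)
  write_marker_csv(s2$markers, f2, p$frame_rate)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- simulate_chew_trial(chew_model_params("A", n_cycles = 2,
                                              missing_rate = 0.02, seed = 99L))
  expect_false(identical(s1$markers, s3$markers))
  expect_gt(sum(is.na(s1$markers$x)), 0)
})

test_that("noiseless cadaver trials have exactly zero joint traces", {
  p <- chew_model_params("A", marker_noise_sigma = 0, cadaver_seconds = 0.5,
                         head_motion_mm = 10, head_motion_deg = 10)
  pr <- precision_analysis(simulate_cadaver_trial(p), config = no_filter())
  expect_true(all(pr$precision$ci < 1e-9))
  vals <- as.matrix(tibble::as_tibble(pr$traces[[1]])[, c("rx", "ry", "rz", "tx", "ty", "tz")])
  expect_lt(max(abs(vals)), 1e-9)
})

test_that("waving amplitude does not affect cadaver precision", {
  base <- function(mm, deg) {
    p <- chew_model_params("A", cadaver_seconds = 2, head_motion_mm = mm,
                           head_motion_deg = deg, seed = 17)
    precision_analysis(simulate_cadaver_trial(p), config = no_filter())$precision
  }
  small <- base(5, 5)
  large <- base(20, 20)
  expect_true(all(abs(large$ci - small$ci) / small$ci < 0.15))
})

test_that("cadaver rotational precision matches the analytic noise oracle", {
  sigma <- 0.05
  p <- chew_model_params("A", marker_noise_sigma = sigma, cadaver_seconds = 4,
                         head_motion_mm = 10, head_motion_deg = 10, seed = 23)
  sim <- simulate_cadaver_trial(p)
  pr <- precision_analysis(sim, config = no_filter())$precision
  # independent small-noise propagation: relative rotation of two noisy
  # bodies; per-axis sd in degrees, t ~ 1.96 at 1000 frames
  sd_c <- rotation_noise_sd(as.matrix(sim$constellations$cranium$markers[, c("x", "y", "z")]), sigma)
  sd_m <- rotation_noise_sd(as.matrix(sim$constellations$right_hemimandible$markers[, c("x", "y", "z")]), sigma)
  oracle <- qt(0.975, 999) * sqrt(sd_c^2 + sd_m^2) * 180 / pi
  got <- pr$ci[match(c("rx", "ry", "rz"), pr$variable)]
  expect_true(all(abs(got - oracle) / oracle < 0.15))
})
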