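injected_map <- function(p) {
  c(condyle_rx = p$roll_amplitude_deg, condyle_ry = p$yaw_amplitude_deg,
    condyle_rz = p$pitch_amplitude_deg, condyle_tx = p$condylar_tx_mm,
    condyle_ty = p$condylar_ty_mm, condyle_tz = p$condylar_tz_mm,
    symphysis_rx = p$symphysis_rx_deg, symphysis_ry = p$symphysis_ry_deg,
    symphysis_rz = p$symphysis_rz_deg, symphysis_tx = p$symphysis_tx_mm,
    symphysis_ty = p$symphysis_ty_mm, symphysis_tz = p$symphysis_tz_mm)
}

test_that("noiseless end-to-end analysis recovers every injected amplitude", {
  p <- tiny_params(n_cycles = 3, head_motion_mm = 2, head_motion_deg = 2)
  fit <- analyze_chew_trial(simulate_chew_trial(p), config = no_filter())
  expect_equal(fit$n_cycles, 3L)
  got <- setNames(fit$summary$mean_amplitude, fit$summary$variable)
  inj <- injected_map(p)
  expect_true(all(abs(got[names(inj)] - inj) / inj < 1e-3))
  # emergent molar amplitudes match the analytic ground-truth trace
  truth_amp <- simulate_chew_trial(p)$kinematics$truth |>
    dplyr::filter(startsWith(variable, "molar")) |>
    dplyr::group_by(variable) |>
    dplyr::summarise(amp = diff(range(value)))
  expect_true(all(abs(got[truth_amp$variable] - truth_amp$amp) /
                    truth_amp$amp < 1e-3))
})

test_that("whole-scene waving leaves every trace unchanged", {
  still <- tiny_params(n_cycles = 3)
  waved <- tiny_params(n_cycles = 3, head_motion_mm = 5, head_motion_deg = 5)
  f1 <- analyze_chew_trial(simulate_chew_trial(still), config = no_filter())
  f2 <- analyze_chew_trial(simulate_chew_trial(waved), config = no_filter())
  expect_equal(f1$zero_frame, f2$zero_frame)
  for (j in c("tmj_right", "tmj_left", "symphysis")) {
    m1 <- as.matrix(tibble::as_tibble(f1$traces[[j]])[, c("rx", "ry", "rz", "tx", "ty", "tz")])
    m2 <- as.matrix(tibble::as_tibble(f2$traces[[j]])[, c("rx", "ry", "rz", "tx", "ty", "tz")])
    expect_lt(max(abs(m1 - m2)), 1e-6)
  }
  mm1 <- as.matrix(tibble::as_tibble(f1$traces$molar)[, c("tx", "ty", "tz")])
  mm2 <- as.matrix(tibble::as_tibble(f2$traces$molar)[, c("tx", "ty", "tz")])
  expect_lt(max(abs(mm1 - mm2)), 1e-6)
})

test_that("mirroring the scene swaps the TMJs and flips lateral polarities", {
  p <- tiny_params(n_cycles = 3)
  sim <- simulate_chew_trial(p)
  # pin the zero frame (a peak-closure frame) so both analyses share it: the
  # data-driven representative-chew choice may differ between the two sides
  cfg <- no_filter(zero_frame = 101L)
  fit <- analyze_chew_trial(sim, config = cfg)

  # reflect through the midsagittal plane (z -> -z) and swap left/right labels
  swap <- function(x) dplyr::recode(x, right_hemimandible = "left_hemimandible",
                                    left_hemimandible = "right_hemimandible")
  mk <- sim$markers |>
    dplyr::mutate(z = -z, body = swap(body))
  lmk <- sim$landmarks |>
    dplyr::mutate(z = -z, body = swap(body),
                  landmark = dplyr::recode(landmark,
                                           condyle_centroid_right = "condyle_centroid_left",
                                           condyle_centroid_left = "condyle_centroid_right")) |>
    dplyr::filter(!(body == "left_hemimandible" & landmark == "molar2_locator"))
  # the mirrored animal's right-side locator: same coordinates as the
  # original right-side point, attached to the relabeled right body
  loc <- sim$landmarks[sim$landmarks$landmark == "molar2_locator", ]
  lmk <- dplyr::bind_rows(lmk, dplyr::mutate(loc, body = "right_hemimandible"))
  cons <- purrr::map(sim$constellations, function(con) {
    marker_constellation(swap(con$body), dplyr::mutate(con$markers, z = -z))
  })
  names(cons) <- purrr::map_chr(cons, "body")
  fit_m <- analyze_chew_trial(mk, cons, lmk, p$frame_rate, config = cfg)

  a <- tibble::as_tibble(fit$traces$tmj_right)
  b <- tibble::as_tibble(fit_m$traces$tmj_left)
  expect_equal(b$rz, a$rz, tolerance = 1e-6)
  expect_equal(b$tx, a$tx, tolerance = 1e-6)
  expect_equal(b$ty, a$ty, tolerance = 1e-6)
  expect_equal(b$rx, -a$rx, tolerance = 1e-6)
  expect_equal(b$ry, -a$ry, tolerance = 1e-6)
  expect_equal(b$tz, -a$tz, tolerance = 1e-6)
})

test_that("tidy/glance expose the summary and run metadata", {
  p <- tiny_params(n_cycles = 3)
  fit <- analyze_chew_trial(simulate_chew_trial(p), config = no_filter())
  td <- tidy(fit)
  expect_true(all(c("variable", "n_cycles", "mean_amplitude", "ci") %in% names(td)))
  expect_equal(sum(!startsWith(td$variable, "tmj_balancing")), 15L)
  gl <- glance(fit)
  expect_equal(gl$n_cycles, 3L)
  expect_equal(gl$frames_removed, 0L)
  expect_true(is.na(gl$cutoff_hz))
})

test_that("multi-individual reports follow the summary-table structure", {
  fits <- purrr::map(c(A = "A", B = "B"), function(ind) {
    analyze_chew_trial(simulate_chew_trial(
      chew_model_params(ind, n_cycles = 3, marker_noise_sigma = 0,
                        head_motion_mm = 0, head_motion_deg = 0)),
      config = no_filter())
  })
  pr <- tibble::tibble(variable = c("rx", "ry", "rz", "tx", "ty", "tz"),
                       ci = rep(0.01, 6), n_frames = 100L)
  rep <- chew_report(fits, precision = pr)
  expect_equal(rep$total_cycles, 6L)
  expect_equal(nrow(rep$table), 3L)            # 2 individuals + workflow row
  expect_equal(sum(startsWith(names(rep$table), "condyle_")), 6L)
  expect_equal(sum(startsWith(names(rep$table), "symphysis_")), 6L)
  expect_equal(sum(startsWith(names(rep$table), "molar_")), 3L)
  expect_equal(nrow(rep$aggregate$group_means), 2L)
  expect_equal(rep$aggregate$group_means$n_entries, c(6L, 6L))

  # reports are reproducible byte for byte
  j1 <- tempfile(fileext = ".json"); j2 <- tempfile(fileext = ".json")
  write_report(rep, json_path = j1, seed = 1)
  write_report(rep, json_path = j2, seed = 1)
  expect_identical(readLines(j1), readLines(j2))
  csv <- tempfile(fileext = ".csv")
  write_report(rep, csv_path = csv)
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)), 3L)
})

test_that("autoplot methods return ggplot objects", {
  p <- tiny_params(n_cycles = 3)
  fit <- analyze_chew_trial(simulate_chew_trial(p), config = no_filter())
  expect_s3_class(autoplot(fit$traces$tmj_right), "ggplot")
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("dropped frames are logged and propagate to cycle handling", {
  p <- chew_model_params("A", n_cycles = 4, marker_noise_sigma = 0.02,
                         head_motion_mm = 0, head_motion_deg = 0,
                         missing_rate = 0.02, seed = 13)
  fit <- analyze_chew_trial(simulate_chew_trial(p))
  expect_s3_class(fit$log$frames_removed, "data.frame")
  expect_gte(fit$n_cycles, 2L)   # most cycles survive mild missingness
  expect_true(all(c("start", "end", "reason") %in% names(fit$log$cycles_dropped)))
})
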