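test_that("find_peaks reports prominences and earliest plateau index", {
  x <- c(0, 1, 0, 3, 2.5, 2.5, 4, 0)
  pk <- find_peaks(x)
  expect_equal(pk$index, c(2L, 4L, 7L))
  expect_equal(pk$prominence[pk$index == 2L], 1)
  # the 3-peak is separated from the higher 4-peak by the 2.5 saddle
  expect_equal(pk$prominence[pk$index == 4L], 0.5)
  plateau <- c(0, 2, 2, 2, 0)
  expect_equal(find_peaks(plateau)$index, 2L)
  expect_equal(nrow(find_peaks(rep(1, 10))), 0L)
})

test_that("synthetic cycles are segmented at gape maxima within one frame", {
  p <- tiny_params(n_cycles = 10)
  sim <- simulate_chew_trial(p)
  fit <- analyze_chew_trial(sim, config = no_filter())
  segs <- fit$segments[fit$segments$kept, ]
  expect_equal(nrow(segs), 10L)
  truth <- sim$kinematics$boundary_frames
  expect_true(all(abs(segs$start - truth[seq_len(nrow(segs))]) <= 1))
  expect_true(all(abs(segs$end - truth[seq_len(nrow(segs)) + 1L]) <= 1))
})

test_that("flat traces yield no cycles and the amplitude gate works", {
  expect_equal(nrow(segment_cycles(rep(0, 500))), 0L)
  # 12-degree chews with one 30-degree gathering cycle in the middle;
  # gape maxima (cycle boundaries) all sit at the same height
  phi <- seq(0, 5, by = 0.01)
  amp <- ifelse(pmin(floor(phi), 4) == 2, 30, 12)
  rz <- -(12 - amp * (1 - cos(2 * pi * phi)) / 2)
  segs <- segment_cycles(rz, min_amplitude_deg = 5, max_amplitude_deg = 25)
  expect_equal(nrow(segs), 3L)   # incomplete first/last cycles never appear
  expect_equal(sum(segs$kept), 2L)
  expect_true(grepl("gathering", segs$reason[!segs$kept]))
})

test_that("normalization preserves ramps, endpoints, and sine shape", {
  ramp <- seq(0, 1, length.out = 73)
  out <- normalize_cycle(ramp)
  expect_equal(out, seq(0, 1, length.out = 100), tolerance = 1e-9)

  t <- seq(0, 2 * pi, length.out = 60)
  out <- normalize_cycle(sin(t))
  truth <- sin(seq(0, 2 * pi, length.out = 100))
  expect_lt(max(abs(out - truth)), 1e-3)
  expect_equal(out[c(1, 100)], sin(t[c(1, 60)]), tolerance = 1e-12)

  gappy <- sin(seq(0, 2 * pi, length.out = 100))
  gappy[40:60] <- NA
  expect_error(normalize_cycle(gappy), class = "chewkin_error_cycle")
  expect_error(normalize_cycle(c(1, 2, NA)), class = "chewkin_error_cycle")
  ends <- c(NA, 1:50)
  expect_error(normalize_cycle(ends), class = "chewkin_error_cycle")
})

test_that("amplitude is max minus min and time-reversal invariant", {
  expect_equal(cycle_amplitude(rep(3, 100)), 0)
  s <- 2.5 * sin(seq(0, 2 * pi, length.out = 100))
  expect_equal(cycle_amplitude(s), 5, tolerance = 1e-3)
  set.seed(71)
  for (i in 1:10) {
    x <- cumsum(rnorm(100))
    expect_equal(cycle_amplitude(x), cycle_amplitude(rev(x)))
  }
})

test_that("occlusal window metrics follow the middle-40% arithmetic", {
  ramp <- seq(0, 2, length.out = 100)
  m <- occlusal_metrics(ramp)
  expect_equal(m[["displacement"]], 0.8, tolerance = 0.02)
  expect_equal(m[["range"]], m[["displacement"]])
  expect_equal(occlusal_metrics(rep(1, 100))[["displacement"]], 0)
})

test_that("between-cycle CI matches closed forms and is zero for identical cycles", {
  base <- sin(seq(0, 2 * pi, length.out = 100))
  cyc <- tidyr::expand_grid(cycle = 1:5, sample = 1:100) |>
    dplyr::mutate(variable = "v", value = base[sample])
  s <- summarize_amplitudes(cyc)
  expect_equal(s$ci, 0, tolerance = 1e-12)
  expect_equal(s$mean_amplitude, cycle_amplitude(base))

  # two cycles offset by a constant: pointwise sd is constant = d/sqrt(2)
  d <- 0.3
  cyc2 <- dplyr::bind_rows(
    tibble::tibble(cycle = 1, variable = "v", sample = 1:100, value = base),
    tibble::tibble(cycle = 2, variable = "v", sample = 1:100, value = base + d))
  s2 <- summarize_amplitudes(cyc2)
  sd2 <- sd(c(0, d))
  expect_equal(s2$ci, qt(0.975, 1) * sd2 / sqrt(2), tolerance = 1e-9)
  # n = 1: CI undefined
  s1 <- summarize_amplitudes(dplyr::filter(cyc2, cycle == 1))
  expect_true(is.na(s1$ci))
  expect_equal(s1$mean_amplitude, cycle_amplitude(base))
})

test_that("between-cycle CI shrinks with cycle count as t_{n-1}/sqrt(n)", {
  set.seed(72)
  base <- sin(seq(0, 2 * pi, length.out = 100))
  sigma <- 0.2
  ns <- c(4, 8, 16, 32, 64)
  mean_ci <- vapply(ns, function(n) {
    cis <- replicate(40, {
      cyc <- tidyr::expand_grid(cycle = seq_len(n), sample = 1:100) |>
        dplyr::mutate(variable = "v",
                      value = base[sample] + rnorm(dplyr::n(), sd = sigma))
      summarize_amplitudes(cyc)$ci
    })
    mean(cis)
  }, numeric(1))
  slope <- coef(lm(log(mean_ci) ~ log(ns)))[[2]]
  # expected slope of log(t_{n-1}/sqrt(n)): 1/sqrt(n) scaling plus the
  # small-sample t correction
  expected <- coef(lm(log(qt(0.975, ns - 1) / sqrt(ns)) ~ log(ns)))[[2]]
  expect_equal(slope, expected, tolerance = 0.1)
  expect_lt(slope, -0.5)
})

test_that("across-individual aggregation reproduces the reference arithmetic", {
  rot <- c(1.10, 1.13, 1.55, 2.09, 0.60, 0.63, 0.99, 1.50, 0.82)
  trn <- c(0.18, 0.62, 0.41, 0.04, 0.36, 0.20, 0.04, 0.06, 0.08)
  summ <- dplyr::bind_rows(
    tibble::tibble(individual = rep(c("A", "B", "C"), each = 3),
                   variable = rep(paste0("symphysis_", c("rx", "ry", "rz")), 3),
                   mean_amplitude = rot),
    tibble::tibble(individual = rep(c("A", "B", "C"), each = 3),
                   variable = rep(paste0("symphysis_", c("tx", "ty", "tz")), 3),
                   mean_amplitude = trn))
  agg <- aggregate_across_individuals(
    summ, groups = list(rot = paste0("symphysis_", c("rx", "ry", "rz")),
                        trn = paste0("symphysis_", c("tx", "ty", "tz"))))
  expect_equal(agg$group_means$mean[agg$group_means$group == "rot"], mean(rot))
  expect_equal(agg$group_means$mean_rounded[agg$group_means$group == "rot"], 1.16)
  expect_equal(round_half_up(agg$group_means$mean[agg$group_means$group == "trn"], 1), 0.2)
  single <- aggregate_across_individuals(summ[summ$individual == "A", ])
  expect_equal(single$ranges$min, single$ranges$max)
})

test_that("workflow precision is zero for exact zero traces and errors on empty", {
  z <- tibble::tibble(frame = 1:50, rx = 0, ry = 0, rz = 0, tx = 0, ty = 0, tz = 0,
                      gimbal = FALSE, missing = FALSE)
  pr <- workflow_precision(z)
  expect_true(all(pr$ci < 1e-12))
  expect_error(workflow_precision(list()), class = "chewkin_error_validation")
})
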