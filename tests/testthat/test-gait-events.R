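test_that("heel strikes of a pure sinusoid fall at the analytic minima", {
  rate <- 100
  t <- seq(0, 20, by = 1 / rate)
  period <- 1.25
  z <- 30 * sin(2 * pi * t / period)
  hs <- detect_heel_strikes(z, rate)
  # minima of sin at 3/4 period + k*period
  expected <- seq(0.75 * period, max(t), by = period)
  expected <- expected[expected <= max(t) - 0.01]
  expect_equal(length(hs), length(expected))
  expect_lt(max(abs(hs - expected)), 1.5 / rate)
  expect_lt(max(abs(diff(hs) - period)), 2.5 / rate)
})

test_that("degenerate trajectories raise errors", {
  expect_error(detect_heel_strikes(rep(1, 500), 100), "constant")
  expect_error(detect_toe_offs(rep(0, 500), 100), "constant")
  t <- seq(0, 0.8, by = 0.01)  # shorter than one cycle of 1 s
  expect_error(detect_heel_strikes(5 * sin(2 * pi * t), 100))
})

test_that("detection is invariant to a constant vertical offset", {
  cfg <- tiny_config()
  kin <- generate_gait_kinematics(cfg, "steady", seed = 3)
  z <- marker_axis(kin$markers, "heel_r", "z")
  expect_identical(detect_heel_strikes(z, 100),
                   detect_heel_strikes(z + 137.5, 100))
  expect_identical(detect_toe_offs(z, 100), detect_toe_offs(z + 137.5, 100))
})

test_that("detected events match generator ground truth across seeds", {
  ok_hs <- tot_hs <- ok_to <- tot_to <- 0
  for (s in 1:6) {
    cond <- if (s %% 2 == 0) "destabilised" else "steady"
    kin <- generate_gait_kinematics(session_config(trial_duration = 60),
                                    cond, seed = s)
    ev <- detect_gait_events(kin$markers)
    tr <- kin$truth
    e_hs <- c(nearest_err(ev$hs_right, tr$hs_right),
              nearest_err(ev$hs_left, tr$hs_left)) * 100
    e_to <- c(nearest_err(ev$to_right, tr$to_right),
              nearest_err(ev$to_left, tr$to_left)) * 100
    ok_hs <- ok_hs + sum(e_hs <= 1 + 1e-6); tot_hs <- tot_hs + length(e_hs)
    ok_to <- ok_to + sum(e_to <= 2 + 1e-6); tot_to <- tot_to + length(e_to)
    # event lists alternate plausibly
    expect_lte(abs(length(ev$to_right) - length(ev$hs_right)), 1)
    expect_lte(abs(length(ev$to_left) - length(ev$hs_left)), 1)
  }
  expect_gte(ok_hs / tot_hs, 0.99)
  expect_gte(ok_to / tot_to, 0.99)
})

test_that("step width evaluates the mediolateral heel separation at heel strikes", {
  ev <- gait_events(hs_left = c(0.5, 1.6), hs_right = c(1.0, 2.1),
                    to_left = c(1.2), to_right = c(0.7, 1.8))
  n <- 300
  left <- rep(-60, n)
  right <- rep(60, n)
  w <- compute_step_width(left, right, ev, 100)
  expect_true(all(w$step_width == 120))
  expect_equal(nrow(w), 4)
  w0 <- compute_step_width(rep(10, n), rep(10, n), ev, 100)
  expect_true(all(w0$step_width == 0))
  ev_bad <- gait_events(hs_left = 5, hs_right = 6, to_left = 5.5,
                        to_right = 5.7)
  expect_error(compute_step_width(left, right, ev_bad, 100), "span")
})

test_that("step width recovers the configured mean", {
  cfg <- session_config(trial_duration = 120)
  kin <- generate_gait_kinematics(cfg, "steady", seed = 11)
  ev <- detect_gait_events(kin$markers)
  w <- compute_step_width(marker_axis(kin$markers, "heel_l", "x"),
                          marker_axis(kin$markers, "heel_r", "x"), ev, 100)
  sem <- sd(w$step_width) / sqrt(nrow(w))
  expect_lt(abs(mean(w$step_width) - 100), 3 * sem + 1)
})

test_that("stride durations are successive differences with input checks", {
  expect_equal(compute_stride_durations(c(0, 1.1, 2.2)), c(1.1, 1.1))
  expect_error(compute_stride_durations(2.5), "two")
  cfg <- session_config(trial_duration = 180,
                        stride_duration_sd = c(steady = 0.05,
                                               destabilised = 0.05))
  kin <- generate_gait_kinematics(cfg, "steady", seed = 13)
  d <- compute_stride_durations(detect_heel_strikes(
    marker_axis(kin$markers, "heel_r", "z"), 100))
  # sample variance of ~160 strides vs truth 0.0025 s^2 (chi-square bounds)
  n <- length(d)
  ratio <- var(d) / 0.0025
  expect_gt(ratio, qchisq(0.005, n - 1) / (n - 1))
  expect_lt(ratio, qchisq(0.995, n - 1) / (n - 1))
})

test_that("spatiotemporal summary windows and moments behave", {
  widths <- c(rep(500, 100), rep(100, 300))  # first strides must be ignored
  durs <- c(rep(9, 50), rep(1.1, 150))
  s <- summarize_spatiotemporal(widths, durs, window = 150L)
  expect_equal(s$step_width_mean, 100)
  expect_equal(s$step_width_var, 0)
  expect_equal(s$stride_duration_mean, 1.1)
  expect_equal(s$stride_duration_var, 0)
  expect_equal(s$n_strides, 150L)
  expect_error(summarize_spatiotemporal(widths, durs, window = 500L),
               "exceeds")
})
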