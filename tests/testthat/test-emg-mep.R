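test_that("band-pass filter has the designed frequency response", {
  rate <- 2000
  t <- seq(0, 4, by = 1 / rate)
  in_band <- sin(2 * pi * 100 * t)
  out <- bandpass_filter(in_band, rate)
  mid <- out[2000:6000]
  expect_lt(abs(max(mid) - 1), 0.01)  # <1% attenuation at 100 Hz

  dc <- bandpass_filter(rep(50, length(t)), rate)
  expect_lt(abs(mean(dc[2000:6000])), 1e-6)

  low <- bandpass_filter(sin(2 * pi * 5 * t), rate)
  expect_lt(max(abs(low[2000:6000])), 0.1)  # >90% attenuation at 5 Hz

  expect_error(bandpass_filter(in_band, 800), "1000")
})

test_that("ongoing EMG excludes the artifact sample and counts the window", {
  rate <- 2000
  x <- rep(3, 1000)
  stim <- 500L
  x[stim] <- 1000  # artifact
  expect_equal(compute_ongoing_emg(x, stim, rate), 3)
  z <- rep(0, 1000)
  z[stim] <- 1000
  expect_equal(compute_ongoing_emg(z, stim, rate), 0)
  # -20..+10 ms at 2000 Hz = 61 samples inclusive, minus the artifact = 60
  w <- rep(0, 1000)
  w[(stim - 40):(stim + 20)] <- 1  # exactly the window
  w[stim] <- 0
  expect_equal(compute_ongoing_emg(w, stim, rate), 1)
  expect_equal(sum(w), 60)
  expect_error(compute_ongoing_emg(x, 10L, rate), "window")
})

test_that("absolute MEP is the 10-60 ms peak-to-peak", {
  rate <- 2000
  x <- rep(0, 2000)
  stim <- 600L
  expect_equal(compute_absolute_mep(x, stim, rate), 0)
  # 200 uV peak-to-peak sinusoid wholly inside the window
  idx <- (stim + 40):(stim + 100)  # 20-50 ms
  x[idx] <- 100 * sin(2 * pi * seq_along(idx) / 20)
  expect_equal(compute_absolute_mep(x, stim, rate),
               max(x[idx]) - min(x[idx]))
  # deflection before 10 ms is ignored
  y <- rep(0, 2000)
  y[(stim + 2):(stim + 10)] <- 500  # 1-5 ms
  expect_equal(compute_absolute_mep(y, stim, rate), 0)
  expect_error(compute_absolute_mep(x, 1990L, rate), "window")
})

test_that("MEP gain follows the ratio contract with a missing-gain flag", {
  expect_equal(compute_mep_gain(200, 10), 20)
  expect_equal(compute_mep_gain(0, 10), 0)
  expect_true(is.na(compute_mep_gain(150, 0)))
  # scale invariance: c * trace leaves the gain unchanged
  rate <- 2000
  set.seed(1)
  x <- rnorm(2000)
  stim <- 700L
  g1 <- compute_mep_gain(compute_absolute_mep(x, stim, rate),
                         compute_ongoing_emg(x, stim, rate))
  g2 <- compute_mep_gain(compute_absolute_mep(5 * x, stim, rate),
                         compute_ongoing_emg(5 * x, stim, rate))
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("injected noise-free MEPs are recovered within one percent", {
  cfg <- tiny_config(trial_duration = 120, emg_noise_amp = 0,
                     mep_amplitude_noise_sd = 0, artifact_amplitude = 0)
  kin <- generate_gait_kinematics(cfg, "steady", seed = 7)
  em <- generate_emg_with_meps(cfg, "steady", kin$truth, seed = 7)
  rec <- extract_stimulation_records(em$emg, em$stimulations$stim_index,
                                     cfg$emg_rate, kin$truth$hs_right)
  for (m in cfg$muscles) {
    r <- rec[rec$muscle == m, ]
    rel <- abs(r$absolute_mep - em$true_meps[, m]) /
      pmax(em$true_meps[, m], 1e-12)
    expect_lt(max(rel), 0.01)
  }
  # stimulation cycle percentages match the scheduled delays
  expect_equal(rec$cycle_pct[rec$muscle == cfg$muscles[1]],
               em$stimulations$cycle_pct, tolerance = 1e-9)
})

test_that("virtual-marker displacement recovers rigid-body offsets", {
  set.seed(4)
  cal <- list(helmet = matrix(rnorm(12, sd = 50), 4),
              head = matrix(rnorm(12, sd = 50), 4),
              virtual = c(10, 20, 30))
  th <- 0.3
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  mv <- function(m, off) t(R %*% t(m)) + matrix(off, nrow(m), 3, byrow = TRUE)
  # identical motion of both sets: zero displacement
  d0 <- compute_virtual_marker_displacement(cal, mv(cal$helmet, c(5, 1, 2)),
                                            mv(cal$head, c(5, 1, 2)))
  expect_lt(max(d0), 1e-9)
  # pure vertical translation of the head set
  d1 <- compute_virtual_marker_displacement(cal, mv(cal$helmet, c(5, 1, 2)),
                                            mv(cal$head, c(5, 1, 8)))
  expect_equal(unname(d1["vertical"]), 6, tolerance = 1e-9)
  expect_lt(d1["horizontal"], 1e-9)
  # random rigid motion with a known injected offset
  off <- c(3, -4, 6)
  d2 <- compute_virtual_marker_displacement(cal, mv(cal$helmet, c(5, 1, 2)),
                                            mv(cal$head, c(5, 1, 2) + off))
  expect_equal(unname(d2["vertical"]), 6, tolerance = 1e-6)
  expect_equal(unname(d2["horizontal"]), 5, tolerance = 1e-6)
  # collinear markers are rejected
  bad <- cal
  bad$head <- cbind(1:4, 2 * (1:4), 3 * (1:4))
  expect_error(compute_virtual_marker_displacement(bad, cal$helmet, cal$head),
               "collinear")
})

test_that("exclusion rules use strict thresholds and the 100-stim minimum", {
  mk <- function(vert, horiz) {
    n <- length(vert)
    structure(data.frame(stim = seq_len(n), stim_time = seq_len(n),
                         cycle_pct = 50, coil_vertical = vert,
                         coil_horizontal = horiz, muscle = "m",
                         ongoing_emg = 1, absolute_mep = 1, mep_gain = 1,
                         included = TRUE),
              class = c("stimulation_records", "data.frame"))
  }
  # exactly at threshold: included (strict inequality)
  r <- apply_exclusions(mk(c(5.0, 5.1, 0), c(10.0, 0, 10.1)))
  expect_equal(r$records$included, c(TRUE, FALSE, FALSE))
  expect_equal(r$n_surviving, 1)
  expect_false(r$participant_included)
  # 120 records, 30 with vertical 6 mm: 90 survive, participant excluded
  vert <- c(rep(6, 30), rep(1, 90))
  r2 <- apply_exclusions(mk(vert, rep(0, 120)))
  expect_equal(r2$n_surviving, 90)
  expect_false(r2$participant_included)
  r3 <- apply_exclusions(mk(rep(1, 120), rep(1, 120)))
  expect_true(r3$participant_included)
  # monotone: lowering thresholds never increases the surviving count
  r4 <- apply_exclusions(mk(vert, rep(0, 120)), vertical_mm = 3)
  expect_lte(r4$n_surviving, r2$n_surviving)
})

test_that("cycle percentage interpolates between right heel strikes", {
  expect_equal(assign_cycle_percentage(0.3, c(0, 1.2)), 25)
  expect_equal(assign_cycle_percentage(0, c(0, 1.2)), 0)
  expect_warning(pct <- assign_cycle_percentage(5, c(0, 1.2)), "outside")
  expect_true(is.na(pct))
})
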