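test_that("fisher transform matches the closed form and is monotone", {
  expect_equal(fisher_transform(0), 0)
  expect_equal(fisher_transform(0.25), atanh(0.5), tolerance = 1e-12)
  expect_equal(fisher_transform(0.25), 0.5493061, tolerance = 1e-6)
  out <- fisher_transform(c(0.1, 0.5, 0.9))
  expect_true(all(diff(out) > 0))
  expect_true(is.finite(fisher_transform(1)))  # clipped, not infinite
  expect_error(fisher_transform(1.2), "0, 1")
})

test_that("treadmill correction reduces to the plain derivative when absent", {
  cfg <- tiny_config()
  kin <- generate_gait_kinematics(cfg, "steady", seed = 4)
  ev <- detect_gait_events(kin$markers)
  c_null <- suppressWarnings(extract_step_cycles(kin$markers, ev, NULL))
  c_zero <- suppressWarnings(
    extract_step_cycles(kin$markers, ev, numeric(nrow(kin$markers$data))))
  expect_equal(c_null$pel_vel, c_zero$pel_vel, tolerance = 1e-12)
})

test_that("noise-free generator betas are recovered exactly", {
  cfg <- tiny_config(trial_duration = 120, epsilon_sd = 0)
  for (cond in c("steady", "destabilised")) {
    kin <- generate_gait_kinematics(cfg, cond, seed = 4)
    ev <- detect_gait_events(kin$markers)
    cyc <- suppressWarnings(
      extract_step_cycles(kin$markers, ev, kin$perturbation$displacement))
    fit <- fit_foot_placement(cyc)
    np <- length(fit$phase)
    expect_equal(fit$beta_position[np], kin$truth$beta_position,
                 tolerance = 1e-9)
    expect_equal(fit$beta_velocity[np], kin$truth$beta_velocity,
                 tolerance = 1e-9)
    expect_equal(fit$r_squared[np], 1, tolerance = 1e-12)
    expect_lt(fit$fp_error, 1e-9)
  }
})

test_that("predictors at the placement instant match generator CoM states", {
  cfg <- tiny_config(trial_duration = 90)
  kin <- generate_gait_kinematics(cfg, "destabilised", seed = 6)
  ev <- detect_gait_events(kin$markers)
  cyc <- suppressWarnings(
    extract_step_cycles(kin$markers, ev, kin$perturbation$displacement))
  tr <- kin$truth$steps
  key <- paste(cyc$steps$side, round(cyc$steps$t_heelstrike, 3))
  tkey <- paste(tr$side, round(tr$t_heelstrike, 3))
  m <- match(key, tkey)
  expect_true(all(!is.na(m)))
  np <- length(cyc$phase)
  # marker noise (0.3 mm) is the only discrepancy allowed
  expect_lt(max(abs(cyc$pel_pos_raw[, np] - tr$pel_pos[m])), 1.5)
  expect_lt(max(abs(cyc$foot_placement_raw - tr$foot_placement[m])), 1.5)
})

test_that("final-phase R^2 matches the analytic explained-variance fraction", {
  cfg <- tiny_config(trial_duration = 120, epsilon_sd = 6)
  kin <- generate_gait_kinematics(cfg, "steady", seed = 5)
  ev <- detect_gait_events(kin$markers)
  cyc <- suppressWarnings(
    extract_step_cycles(kin$markers, ev, kin$perturbation$displacement))
  fit <- fit_foot_placement(cyc)
  np <- length(fit$phase)
  xb <- cyc$pel_pos[, np] * kin$truth$beta_position +
    cyc$pel_vel[, np] * kin$truth$beta_velocity
  analytic <- var(xb) / (var(xb) + 36)
  expect_lt(abs(fit$r_squared[np] - analytic), 0.1)
})

test_that("null betas give the OLS inflation E[R^2] ~ 2/(n-1)", {
  cfg <- tiny_config(trial_duration = 120,
                     beta_position = 0, beta_velocity = 0,
                     epsilon_sd = 6)
  r2 <- fp <- numeric(6)
  for (s in 1:6) {
    kin <- generate_gait_kinematics(cfg, "steady", seed = 40 + s)
    ev <- detect_gait_events(kin$markers)
    cyc <- suppressWarnings(
      extract_step_cycles(kin$markers, ev, kin$perturbation$displacement))
    fit <- fit_foot_placement(cyc)
    np <- length(fit$phase)
    r2[s] <- fit$r_squared[np]
    fp[s] <- fit$fp_error / sd(cyc$foot_placement)
  }
  n <- 200  # ~steps per 120 s trial
  expect_lt(abs(mean(r2) - 2 / (n - 1)), 0.03)
  expect_lt(abs(mean(fp) - 1), 0.05)
})

test_that("R^2 is invariant to positive rescaling and OLS decomposition holds", {
  set.seed(8)
  n <- 60
  pos <- matrix(rnorm(n * 3), n)
  vel <- matrix(rnorm(n * 3), n)
  y <- 0.5 * pos[, 3] + 0.2 * vel[, 3] + rnorm(n, 0, 0.5)
  mk <- function(scale) {
    structure(list(phase = c(0, 50, 100),
                   pel_pos = pos * scale, pel_vel = vel * scale,
                   foot_placement = (y - mean(y)) * scale,
                   pel_pos_raw = pos, pel_vel_raw = vel,
                   foot_placement_raw = y,
                   steps = data.frame(side = rep("right", n))),
              class = "step_cycle_matrix")
  }
  f1 <- fit_foot_placement(mk(1))
  f2 <- fit_foot_placement(mk(4.2))
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
  # variance decomposition at the placement instant
  yv <- f1$foot_placement
  expl <- var(f1$beta_position[3] * pos[, 3] + f1$beta_velocity[3] * vel[, 3] +
                f1$epsilon[, 3])
  expect_equal(var((y - mean(y))), var(y), tolerance = 1e-12)
  resid_ss <- sum(f1$epsilon[, 3]^2)
  fitted <- (y - mean(y)) - f1$epsilon[, 3]
  expect_equal(sum((y - mean(y))^2), sum(fitted^2) + resid_ss +
                 2 * sum(fitted * f1$epsilon[, 3]), tolerance = 1e-9)
  expect_lt(abs(sum(fitted * f1$epsilon[, 3])), 1e-8)
})

test_that("collinear predictors are flagged, not fitted", {
  n <- 40
  set.seed(2)
  x <- rnorm(n)
  cyc <- structure(list(phase = c(0, 100),
                        pel_pos = cbind(x, x), pel_vel = cbind(x, x),
                        foot_placement = rnorm(n),
                        steps = data.frame(side = rep("right", n))),
                   class = "step_cycle_matrix")
  fit <- fit_foot_placement(cyc)
  expect_true(all(is.na(fit$r_squared)))
  expect_error(fit_foot_placement(structure(list(
    phase = c(0, 100), pel_pos = cbind(x, x)[1:5, ],
    pel_vel = cbind(x, x)[1:5, ], foot_placement = rnorm(5),
    steps = data.frame(side = rep("right", 5))),
    class = "step_cycle_matrix")), "10 steps")
})
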