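#' Pseudorandom mediolateral platform oscillation
#'
#' Builds the band-limited pseudorandom lateral displacement of the treadmill
#' surface as a sum of sinusoids with randomly drawn (hence mutually
#' incommensurate) frequencies in 0.1-1.0 Hz, zero-centred and rescaled so
#' that `max - min` equals `peak_to_peak` exactly.
#'
#' @param duration signal length (s).
#' @param rate sampling rate (Hz).
#' @param peak_to_peak target peak-to-peak amplitude (mm); 0 gives an
#'   identically zero signal.
#' @param seed RNG seed (frequencies, amplitudes and phases).
#' @param n_components number of sinusoids summed.
#' @return data frame with columns `time` (s) and `displacement` (mm).
#' @export
generate_perturbation_signal <- function(duration, rate, peak_to_peak,
                                         seed = 1L, n_components = 12L) {
  check_positive(duration, "duration")
  check_positive(rate, "rate")
  check_nonneg(peak_to_peak, "peak_to_peak")
  t <- seq(0, duration, by = 1 / rate)
  t <- t[t < duration + 1e-9]
  x <- numeric(length(t))
  if (peak_to_peak > 0) {
    with_seed(seed, {
      f <- runif(n_components, 0.1, 1.0)
      a <- runif(n_components, 0.5, 1.0)
      ph <- runif(n_components, 0, 2 * pi)
      for (i in seq_len(n_components)) {
        x <- x + a[i] * sin(2 * pi * f[i] * t + ph[i])
      }
    })
    x <- x - mean(x)
    x <- x * (peak_to_peak / (max(x) - min(x)))
  }
  data.frame(time = t, displacement = x)
}

# --- heel vertical template ---------------------------------------------
# Smooth periodic template z(phi), phi in [0,1) with phi = 0 at heel strike:
# a small heel-pad dip (unique minimum at phi = 0) plus a swing bump whose
# ACCELERATION profile is designed directly: a sharp symmetric positive
# peak just after heel-off (the template's toe-off, and the event
# detector's target; a symmetric peak is not displaced by zero-phase
# smoothing), a broad negative lobe around swing apex, and a smaller
# positive landing peak. Two amplitudes are solved so the profile has zero
# mean and zero first moment, which makes the double integral return to
# zero height and zero velocity at the next heel strike.
HEEL_STANCE_FRACTION <- 0.6
HEEL_DIP_MM <- 3      # depth of the contact notch at heel strike
HEEL_DIP_W <- 0.015   # notch width (fraction of the cycle)
HEEL_SWING_MM <- 60

heel_template_env <- new.env(parent = emptyenv())

build_heel_template <- function() {
  if (!is.null(heel_template_env$b)) return(invisible())
  ng <- 4000L
  u <- seq(0, 1, length.out = ng)
  g <- function(c0, w) exp(-((u - c0) / w)^2 / 2)
  g1 <- g(0.12, 0.05)   # toe-off acceleration peak
  g2 <- g(0.50, 0.18)   # apex deceleration (amplitude solved)
  g3 <- g(0.88, 0.15)   # landing peak (amplitude solved, kept broad/low)
  m0 <- function(x) mean(x)
  m1 <- function(x) mean(x * u)
  # solve a1*g1 - a2*g2 + a3*g3 with a1 = 1 for zero mean & first moment
  M <- matrix(c(-m0(g2), m0(g3), -m1(g2), m1(g3)), 2, 2, byrow = TRUE)
  rhs <- -c(m0(g1), m1(g1))
  a23 <- solve(M, rhs)
  acc <- g1 - a23[1] * g2 + a23[2] * g3
  du <- u[2] - u[1]
  vel <- cumsum(acc) * du
  pos <- cumsum(vel) * du
  s <- 1 / max(pos)
  heel_template_env$u <- u
  heel_template_env$b <- pos * s
  heel_template_env$bdd <- acc * s
  # template toe-off: global argmax of the swing acceleration
  heel_template_env$toeoff_u <- u[which.max(acc)]
  invisible()
}

heel_template_z <- function(phi) {
  build_heel_template()
  phi <- phi %% 1
  d <- pmin(phi, 1 - phi)  # circular distance to heel strike
  z <- HEEL_DIP_MM * (1 - exp(-d^2 / (2 * HEEL_DIP_W^2)))
  sw <- phi >= HEEL_STANCE_FRACTION
  u <- (phi[sw] - HEEL_STANCE_FRACTION) / (1 - HEEL_STANCE_FRACTION)
  z[sw] <- z[sw] + HEEL_SWING_MM *
    approx(heel_template_env$u, heel_template_env$b, xout = u)$y
  z
}

heel_template_zdd <- function(phi) {
  build_heel_template()
  phi <- phi %% 1
  d <- pmin(phi, 1 - phi)
  w <- HEEL_DIP_W
  z <- HEEL_DIP_MM * exp(-d^2 / (2 * w^2)) * (1 / w^2 - d^2 / w^4)
  sw <- phi >= HEEL_STANCE_FRACTION
  sf <- 1 - HEEL_STANCE_FRACTION
  u <- (phi[sw] - HEEL_STANCE_FRACTION) / sf
  z[sw] <- z[sw] + HEEL_SWING_MM *
    approx(heel_template_env$u, heel_template_env$bdd, xout = u)$y / sf^2
  z
}

# Phase (fraction of the cycle) of the template's peak upward acceleration.
heel_template_toeoff_phase <- function() {
  build_heel_template()
  HEEL_STANCE_FRACTION +
    heel_template_env$toeoff_u * (1 - HEEL_STANCE_FRACTION)
}

# Draw a strictly positive stride-duration sequence filling `duration`,
# leaving a margin of trailing data after the final heel strike.
draw_stride_times <- function(duration, mean_s, sd_s, start) {
  hs <- start
  durs <- numeric(0)
  repeat {
    T_k <- rnorm(1, mean_s, sd_s)
    T_k <- min(max(T_k, 0.5 * mean_s), 1.5 * mean_s)
    if (hs[length(hs)] + T_k > duration - 0.3) break
    durs <- c(durs, T_k)
    hs <- c(hs, hs[length(hs)] + T_k)
  }
  list(hs = hs, durations = durs)
}

# Continuous stride-phase function for one leg from its heel-strike times:
# phi(t) crosses integer k at hs[k+1] and advances linearly within strides.
stride_phase <- function(t, hs) {
  n <- length(hs)
  durs <- diff(hs)
  first_T <- durs[1]
  last_T <- durs[length(durs)]
  phi <- numeric(length(t))
  idx <- findInterval(t, hs)
  before <- idx == 0
  phi[before] <- (t[before] - hs[1]) / first_T
  inside <- idx >= 1 & idx < n
  phi[inside] <- (idx[inside] - 1) + (t[inside] - hs[idx[inside]]) / durs[idx[inside]]
  after <- idx == n
  phi[after] <- (n - 1) + pmin((t[after] - hs[n]) / last_T, 0.97)
  phi
}

smoothstep <- function(u) u * u * (3 - 2 * u)

#' Generate synthetic gait kinematics with known ground truth
#'
#' Builds labelled marker trajectories (heels, posterior superior iliac
#' spines, C7, acromions) for one participant-condition trial together with
#' the generating ground truth. Heel vertical trajectories follow a smooth
#' periodic template whose per-cycle minimum falls exactly at the true heel
#' strike and whose peak upward acceleration defines the true toe-off.
#' Mediolateral foot placement at each heel strike follows the linear
#' CoM-feedback law
#' `FP = beta_pos * PELpos + beta_vel * PELvel + eps`, with the pelvis
#' (mean of the two PSIS markers) as CoM proxy, states taken relative to the
#' previous stance foot at contralateral toe-off, and velocity expressed
#' relative to the (possibly oscillating) support surface.
#'
#' @param config a [session_config()].
#' @param condition `"steady"` or `"destabilised"`.
#' @param seed RNG seed for this trial.
#' @return list with elements `markers` (a `marker_series`), `perturbation`
#'   (data frame `time`, `displacement` in mm) and `truth` (a
#'   `gait_ground_truth` list: events, per-step placement table, betas).
#' @export
generate_gait_kinematics <- function(config, condition = "steady", seed = 1L) {
  validate_session_config(config)
  condition <- match.arg(condition, conditions())
  rate <- config$marker_rate
  dur <- config$trial_duration
  pert <- generate_perturbation_signal(
    dur, rate, cond_par(config, "perturbation_peak_to_peak", condition),
    seed = child_seed(seed, "perturbation"))
  t <- pert$time
  n <- length(t)
  d <- pert$displacement
  d_vel <- central_diff(d, rate)

  sd_T <- cond_par(config, "stride_duration_sd", condition)
  mean_T <- cond_par(config, "stride_duration_mean", condition)
  W <- cond_par(config, "step_width_mean", condition)
  beta_pos <- cond_par(config, "beta_position", condition)
  beta_vel <- cond_par(config, "beta_velocity", condition)
  eps_sd <- sqrt(cond_par(config, "epsilon_sd", condition)^2 +
                   cond_par(config, "step_width_sd", condition)^2)

  with_seed(child_seed(seed, paste0("kin-", condition)), {
    # --- event times (snapped to the marker sample grid) ---
    right <- draw_stride_times(dur, mean_T, sd_T, start = 0.30)
    hs_r <- round(right$hs * rate) / rate
    # left heel strikes near mid-cycle of the right stride (small jitter),
    # which keeps the two legs phase-locked over long trials
    jit <- if (sd_T > 0) rnorm(length(hs_r) - 1, 0, 0.1 * sd_T) else 0
    hs_l <- hs_r[-length(hs_r)] + 0.5 * diff(hs_r) + jit
    hs_l <- round(hs_l * rate) / rate
    phi_to <- heel_template_toeoff_phase()
    to_r <- hs_r[-length(hs_r)] + phi_to * diff(hs_r)
    to_l <- hs_l[-length(hs_l)] + phi_to * diff(hs_l)
    # partial-cycle toe-offs: before the first and after the last heel
    # strike (both present in the rendered trajectory)
    edge_to <- function(hs, to) {
      n_h <- length(hs)
      t_lead <- hs[1] - (1 - phi_to) * (hs[2] - hs[1])
      t_trail <- hs[n_h] + phi_to * (hs[n_h] - hs[n_h - 1])
      if (t_lead > 0.05) to <- c(t_lead, to)
      if (t_trail < dur - 0.05) to <- c(to, t_trail)
      to
    }
    to_r <- edge_to(hs_r, to_r)
    to_l <- edge_to(hs_l, to_l)

    # --- heel vertical from the template ---
    phi_r <- stride_phase(t, hs_r)
    phi_l <- stride_phase(t, hs_l)
    heel_r_z <- heel_template_z(phi_r)
    heel_l_z <- heel_template_z(phi_l)

    # --- pelvis / thorax mediolateral ---
    global_phase <- phi_r  # right-HS-referenced cycle phase
    sway <- cond_par(config, "sway_amplitude", condition) *
      sin(2 * pi * global_phase)
    p_noise <- lowpass_zero_phase(rnorm(n), rate, 1.5)
    p_noise <- p_noise / max(sd(p_noise), 1e-12) *
      cond_par(config, "sway_noise_sd", condition)
    pelvis <- sway + config$perturbation_coupling * d + p_noise
    pelvis_vel <- central_diff(pelvis, rate)

    th_noise <- lowpass_zero_phase(rnorm(n), rate, 2.0)
    th_noise <- th_noise / max(sd(th_noise), 1e-12) *
      cond_par(config, "thorax_noise_sd", condition)
    thorax <- 0.8 * sway + config$perturbation_coupling * d + th_noise

    # --- sequential foot placement following the control law ---
    all_hs <- rbind(data.frame(time = hs_r, side = "right"),
                    data.frame(time = hs_l, side = "left"))
    all_hs <- all_hs[order(all_hs$time), ]
    to_list <- list(right = to_r, left = to_l)
    place <- list(right = numeric(0), left = numeric(0))  # lab ML at placement
    place_t <- list(right = numeric(0), left = numeric(0))
    x_stance <- list(right = W / 2, left = -W / 2)
    x_stance_t <- list(right = t[1], left = t[1])
    steps <- list()
    for (k in seq_len(nrow(all_hs))) {
      s <- all_hs$side[k]
      o <- if (s == "right") "left" else "right"
      t_hs <- all_hs$time[k]
      sgn <- if (s == "right") 1 else -1
      # toe-off of the placing foot that starts this swing
      prev_to <- to_list[[s]][to_list[[s]] < t_hs]
      t_to <- if (length(prev_to)) max(prev_to) else NA_real_
      idx_hs <- round((t_hs - t[1]) * rate) + 1
      init <- is.na(t_to)
      # lab position of the stance (other) foot at swing start, riding the
      # belt since its own placement (or since trial start before it)
      if (init) {
        origin <- x_stance[[o]]
      } else {
        idx_to <- round((t_to - t[1]) * rate) + 1
        idx_pl <- round((x_stance_t[[o]] - t[1]) * rate) + 1
        origin <- x_stance[[o]] + d[idx_to] - d[idx_pl]
      }
      delta <- pelvis[idx_hs] - origin
      vel <- pelvis_vel[idx_hs] - d_vel[idx_hs]
      # centring constants of the placement law: nominal pelvis offset of
      # half a step width, and the phase-locked sway velocity at contact
      # (the pelvis moves towards the landing side at heel strike); any
      # fixed centring leaves the regression coefficients identifiable,
      # but these keep the mean step width at the configured value
      c_vel <- sgn * 2 * pi *
        cond_par(config, "sway_amplitude", condition) / mean_T
      if (init) {
        fp <- sgn * W
        eps <- NA_real_
      } else {
        eps <- rnorm(1, 0, eps_sd)
        fp <- sgn * W + beta_pos * (delta - sgn * W / 2) +
          beta_vel * (vel - c_vel) + eps
      }
      x_new <- origin + fp
      place[[s]] <- c(place[[s]], x_new)
      place_t[[s]] <- c(place_t[[s]], t_hs)
      x_stance[[s]] <- x_new
      x_stance_t[[s]] <- t_hs
      steps[[length(steps) + 1]] <- data.frame(
        side = s, t_toeoff = t_to, t_heelstrike = t_hs, origin = origin,
        pel_pos = delta, pel_vel = vel, foot_placement = fp,
        epsilon = eps, initial = init)
    }
    steps <- do.call(rbind, steps)

    # --- continuous heel ML trajectories ---
    heel_ml <- function(side) {
      pt <- place_t[[side]]
      pv <- place[[side]]
      x <- numeric(n)
      to_s <- to_list[[side]]
      # before the first placement: initial stance riding the belt, then
      # (if a lead-in toe-off exists) a swing into the first placement
      x_init <- if (side == "right") W / 2 else -W / 2
      pre <- t < pt[1]
      x[pre] <- x_init + d[pre] - d[1]
      lead <- to_s[to_s < pt[1]]
      if (length(lead)) {
        t_lift <- max(lead)
        sw <- t >= t_lift & pre
        if (any(sw)) {
          i_l <- round((t_lift - t[1]) * rate) + 1L
          x_lift <- x_init + d[i_l] - d[1]
          u <- (t[sw] - t_lift) / (pt[1] - t_lift)
          x[sw] <- x_lift + (pv[1] - x_lift) * smoothstep(pmin(u, 1))
        }
      }
      for (k in seq_along(pt)) {
        t0 <- pt[k]
        t1 <- if (k < length(pt)) pt[k + 1] else t[n] + 1
        seg <- t >= t0 & t < t1
        if (!any(seg)) next
        # stance: ride the belt from the placement instant
        i0 <- round((t0 - t[1]) * rate) + 1
        to_k <- to_s[to_s > t0 & to_s < t1]
        t_lift <- if (length(to_k)) min(to_k) else t1
        ts <- t[seg]
        xs <- pv[k] + d[which(seg)] - d[i0]
        if (k < length(pt) && t_lift < t1) {
          sw <- ts >= t_lift
          if (any(sw)) {
            i_l <- round((t_lift - t[1]) * rate) + 1
            x_lift <- pv[k] + d[min(i_l, n)] - d[i0]
            u <- (ts[sw] - t_lift) / (t1 - t_lift)
            xs[sw] <- x_lift + (pv[k + 1] - x_lift) * smoothstep(pmin(u, 1))
          }
        }
        x[seg] <- xs
      }
      x
    }
    heel_r_x <- heel_ml("right")
    heel_l_x <- heel_ml("left")

    # --- assemble markers (ML = x, AP = y, vertical = z; mm) ---
    mn <- function() if (config$marker_noise_sd > 0)
      rnorm(n, 0, config$marker_noise_sd) else numeric(n)
    ap_r <- 120 * cos(2 * pi * phi_r)
    ap_l <- 120 * cos(2 * pi * phi_l)
    markers <- data.frame(
      time = t,
      heel_r_x = heel_r_x + mn(), heel_r_y = ap_r + mn(),
      heel_r_z = heel_r_z + 30 + mn(),
      heel_l_x = heel_l_x + mn(), heel_l_y = ap_l + mn(),
      heel_l_z = heel_l_z + 30 + mn(),
      psis_r_x = pelvis + 40 + mn(), psis_r_y = mn(),
      psis_r_z = 1000 + mn(),
      psis_l_x = pelvis - 40 + mn(), psis_l_y = mn(),
      psis_l_z = 1000 + mn(),
      c7_x = thorax + mn(), c7_y = -30 + mn(), c7_z = 1450 + mn(),
      acrom_r_x = thorax + 150 + mn(), acrom_r_y = mn(),
      acrom_r_z = 1400 + mn(),
      acrom_l_x = thorax - 150 + mn(), acrom_l_y = mn(),
      acrom_l_z = 1400 + mn()
    )
    truth <- structure(list(
      condition = condition,
      hs_right = hs_r, hs_left = hs_l,
      to_right = to_r, to_left = to_l,
      stride_durations_right = diff(hs_r),
      steps = steps,
      beta_position = beta_pos, beta_velocity = beta_vel,
      epsilon_sd = eps_sd, step_width = W,
      toeoff_phase = phi_to, marker_rate = rate
    ), class = "gait_ground_truth")
    list(markers = new_marker_series(markers, rate),
         perturbation = pert, truth = truth)
  })
}

#' Labelled marker time series
#'
#' Thin S3 container for wide-format marker trajectories: a data frame with
#' a `time` column plus `<marker>_<axis>` columns in millimetres, and the
#' sampling rate as an attribute.
#'
#' @param data wide data frame (`time` + `<marker>_<axis>` columns, mm).
#' @param rate sampling rate (Hz).
#' @return object of class `marker_series`.
#' @export
new_marker_series <- function(data, rate) {
  stopifnot(is.data.frame(data), "time" %in% names(data))
  check_positive(rate, "rate")
  structure(list(data = data, rate = rate), class = "marker_series")
}

#' @export
print.marker_series <- function(x, ...) {
  cat(sprintf("<marker_series> %d samples @ %g Hz, %d channels\n",
              nrow(x$data), x$rate, ncol(x$data) - 1L))
  cat("  markers:", paste(unique(sub("_[xyz]$", "",
                                     setdiff(names(x$data), "time"))),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Extract one marker axis from a marker series
#'
#' @param series a `marker_series`.
#' @param marker marker name, e.g. `"heel_r"`.
#' @param axis `"x"` (mediolateral), `"y"` (anteroposterior) or `"z"`
#'   (vertical).
#' @return numeric vector (mm).
#' @export
marker_axis <- function(series, marker, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  col <- paste0(marker, "_", axis)
  if (!col %in% names(series$data)) {
    stop_invalid("marker column `%s` not present", col)
  }
  series$data[[col]]
}

#' @export
print.gait_ground_truth <- function(x, ...) {
  cat(sprintf("<gait_ground_truth> condition %s: %d right / %d left heel strikes, %d modelled steps\n",
              x$condition, length(x$hs_right), length(x$hs_left),
              sum(!x$steps$initial)))
  invisible(x)
}
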