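#' Extract per-step CoM-state/foot-placement matrices over the step cycle
#'
#' For every step (contralateral toe-off to heel strike of the placing
#' foot), the pelvis mediolateral position (mean of the two posterior
#' superior iliac spine markers) is expressed relative to the stance-foot
#' heel position at the step start, and resampled onto a fixed phase grid
#' spanning the single-leg-stance phase. The pelvis velocity is the time
#' derivative of that position minus the lateral velocity of the treadmill
#' surface when a displacement signal is supplied (velocity relative to the
#' support surface). The outcome is the mediolateral heel position of the
#' placing foot at heel strike in the same frame.
#'
#' @param markers a `marker_series` with heel and PSIS markers.
#' @param events a [gait_events()] object.
#' @param treadmill_displacement optional lateral platform displacement (mm)
#'   sampled on the marker clock; `NULL` or all-zero means a stationary
#'   surface.
#' @param side `"right"`, `"left"` or `"both"` (steps pooled in time order).
#' @param n_phase number of phase-grid points from toe-off (0%) to heel
#'   strike (100%).
#' @return object of class `step_cycle_matrix`: `pel_pos`, `pel_vel`
#'   (steps x phase, demeaned per phase point), `foot_placement` (demeaned,
#'   mm), `phase` (%), plus the raw (undemeaned) copies.
#' @export
extract_step_cycles <- function(markers, events, treadmill_displacement = NULL,
                                side = c("both", "right", "left"),
                                n_phase = 51L) {
  side <- match.arg(side)
  rate <- markers$rate
  pelvis <- (marker_axis(markers, "psis_l", "x") +
               marker_axis(markers, "psis_r", "x")) / 2
  n <- length(pelvis)
  t <- (seq_len(n) - 1L) / rate
  if (is.null(treadmill_displacement)) treadmill_displacement <- numeric(n)
  if (length(treadmill_displacement) != n) {
    stop_invalid("treadmill displacement must match the marker series length")
  }
  pel_vel_lab <- central_diff(pelvis, rate)
  surf_vel <- central_diff(treadmill_displacement, rate)
  heel <- list(right = marker_axis(markers, "heel_r", "x"),
               left = marker_axis(markers, "heel_l", "x"))

  sides <- if (side == "both") c("right", "left") else side
  rows <- list()
  meta <- list()
  for (s in sides) {
    o <- if (s == "right") "left" else "right"
    hs <- events[[paste0("hs_", s)]]
    to <- events[[paste0("to_", s)]]
    T_med <- median(diff(hs))
    n_skipped <- 0L
    for (t_hs in hs) {
      prev_to <- to[to < t_hs]
      if (!length(prev_to)) next
      t_to <- max(prev_to)
      # the single-leg-stance window is a substantial fraction of the
      # stride; windows outside this range are boundary/detection artifacts
      if (t_hs - t_to < 0.15 * T_med || t_hs - t_to > 0.7 * T_med) {
        n_skipped <- n_skipped + 1L
        next
      }
      i_to <- round(t_to * rate) + 1L
      i_hs <- round(t_hs * rate) + 1L
      if (i_to < 1L || i_hs > n) next
      origin <- heel[[o]][i_to]
      tt <- t_to + (t_hs - t_to) * seq(0, 1, length.out = n_phase)
      pos <- approx(t, pelvis, xout = tt)$y - origin
      vel <- approx(t, pel_vel_lab - surf_vel, xout = tt)$y
      fp <- heel[[s]][i_hs] - origin
      rows[[length(rows) + 1L]] <- list(pos = pos, vel = vel, fp = fp)
      meta[[length(meta) + 1L]] <- data.frame(side = s, t_toeoff = t_to,
                                              t_heelstrike = t_hs)
    }
    if (n_skipped > 0L) {
      warning(sprintf("%d %s step(s) skipped: implausible swing window",
                      n_skipped, s), call. = FALSE)
    }
  }
  if (length(rows) < 2L) stop_invalid("fewer than two usable steps")
  pos <- do.call(rbind, lapply(rows, `[[`, "pos"))
  vel <- do.call(rbind, lapply(rows, `[[`, "vel"))
  fp <- vapply(rows, `[[`, numeric(1), "fp")
  meta <- do.call(rbind, meta)
  # demean within side: left and right steps carry opposite-sign offsets
  # of the pelvis relative to the stance foot, which the common placement
  # law does not model
  pos_d <- pos
  vel_d <- vel
  fp_d <- fp
  for (s in unique(meta$side)) {
    i <- meta$side == s
    pos_d[i, ] <- sweep(pos[i, , drop = FALSE], 2,
                        colMeans(pos[i, , drop = FALSE]))
    vel_d[i, ] <- sweep(vel[i, , drop = FALSE], 2,
                        colMeans(vel[i, , drop = FALSE]))
    fp_d[i] <- fp[i] - mean(fp[i])
  }
  structure(list(
    phase = seq(0, 100, length.out = n_phase),
    pel_pos = pos_d,
    pel_vel = vel_d,
    foot_placement = fp_d,
    pel_pos_raw = pos, pel_vel_raw = vel, foot_placement_raw = fp,
    steps = meta
  ), class = "step_cycle_matrix")
}

#' @export
print.step_cycle_matrix <- function(x, ...) {
  cat(sprintf("<step_cycle_matrix> %d steps x %d phase points\n",
              nrow(x$pel_pos), length(x$phase)))
  invisible(x)
}

#' Fit the foot-placement-control model over the step cycle
#'
#' At every phase point, ordinary least squares of the demeaned mediolateral
#' foot placement on the demeaned pelvis position and velocity (no
#' intercept; demeaning absorbs it):
#' `FP = beta_pos(t) * PELpos(t) + beta_vel(t) * PELvel(t) + eps(t)`.
#' `r_squared(t)` is the relative explained variance; the foot-placement
#' error is the standard deviation of the residual at the final phase point
#' (the placement instant).
#'
#' @param cycles a `step_cycle_matrix`.
#' @return object of class `foot_placement_fit`: per-phase `beta_position`,
#'   `beta_velocity`, their standard errors, `r_squared`, `fisher`
#'   (Fisher-transformed R, i.e. `atanh(sqrt(R^2))`), residual matrix
#'   `epsilon`, and scalar `fp_error` (mm).
#' @export
fit_foot_placement <- function(cycles) {
  np <- length(cycles$phase)
  n <- nrow(cycles$pel_pos)
  if (n < 10L) stop_invalid("need at least 10 steps to fit the model")
  y <- cycles$foot_placement
  bp <- bv <- r2 <- se_p <- se_v <- rep(NA_real_, np)
  eps <- matrix(NA_real_, n, np)
  tss <- sum(y^2)
  for (j in seq_len(np)) {
    X <- cbind(cycles$pel_pos[, j], cycles$pel_vel[, j])
    xtx <- crossprod(X)
    if (any(!is.finite(xtx)) || abs(det(xtx)) < 1e-10 * max(diag(xtx))^2 ||
        any(diag(xtx) == 0)) {
      next  # collinear or zero-variance predictors: flagged phase point
    }
    b <- solve(xtx, crossprod(X, y))
    res <- y - X %*% b
    eps[, j] <- res
    bp[j] <- b[1]
    bv[j] <- b[2]
    r2[j] <- max(0, min(1, 1 - sum(res^2) / tss))
    s2 <- sum(res^2) / (n - 2L)
    covb <- s2 * solve(xtx)
    se_p[j] <- sqrt(covb[1, 1])
    se_v[j] <- sqrt(covb[2, 2])
  }
  structure(list(
    phase = cycles$phase,
    beta_position = bp, beta_velocity = bv,
    se_position = se_p, se_velocity = se_v,
    r_squared = r2,
    fisher = fisher_transform(r2),
    epsilon = eps,
    fp_error = sd(eps[, np]),
    n_steps = n
  ), class = "foot_placement_fit")
}

#' @export
print.foot_placement_fit <- function(x, ...) {
  np <- length(x$phase)
  cat(sprintf(paste0("<foot_placement_fit> %d steps\n",
                     "  final-phase beta_pos %.3f, beta_vel %.3f, R^2 %.3f\n",
                     "  foot-placement error %.2f mm\n"),
              x$n_steps, x$beta_position[np], x$beta_velocity[np],
              x$r_squared[np], x$fp_error))
  invisible(x)
}

#' Fisher transform of explained variance
#'
#' `atanh(sqrt(r_squared))`, the Fisher z-transform of the multiple
#' correlation R, applied to normalise R-squared curves before testing.
#' Values are clipped just below one to keep the transform finite.
#'
#' @param r_squared values in `[0, 1]` (NAs pass through).
#' @return transformed values (monotone in the input).
#' @export
fisher_transform <- function(r_squared) {
  if (any(r_squared < 0 | r_squared > 1, na.rm = TRUE)) {
    stop_invalid("r_squared values must lie in [0, 1]")
  }
  atanh(sqrt(pmin(r_squared, 1 - 1e-12)))
}
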