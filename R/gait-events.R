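#' Gait events container
#'
#' @param hs_left,hs_right,to_left,to_right strictly increasing event times
#'   (s) per side.
#' @return object of class `gait_events`.
#' @export
gait_events <- function(hs_left, hs_right, to_left, to_right) {
  for (v in list(hs_left, hs_right, to_left, to_right)) {
    if (length(v) > 1 && any(diff(v) <= 0)) {
      stop_invalid("event times must be strictly increasing")
    }
  }
  structure(list(hs_left = hs_left, hs_right = hs_right,
                 to_left = to_left, to_right = to_right),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> HS right/left: %d/%d, TO right/left: %d/%d\n",
              length(x$hs_right), length(x$hs_left),
              length(x$to_right), length(x$to_left)))
  invisible(x)
}

# Median cycle period (samples) from the autocorrelation of the centred
# signal: the first local acf maximum past the first zero crossing.
estimate_period_samples <- function(x, rate) {
  x <- x - mean(x)
  if (sd(x) == 0) stop_invalid("constant trajectory: no gait events")
  max_lag <- min(length(x) - 2L, as.integer(5 * rate))
  a <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE)$acf)
  # first lag where acf dips below zero, then the maximum after it
  below <- which(a < 0)
  if (!length(below)) stop_invalid("no periodicity found in trajectory")
  i0 <- below[1]
  seg <- a[i0:length(a)]
  per <- i0 - 1L + which.max(seg) - 1L
  if (per < 2L) stop_invalid("no plausible stride period found")
  per
}

# Local extrema (strict neighbours) of a series, value-ordered greedy
# selection under a minimum separation constraint; `thresh` (on the
# possibly negated scale) discards shallow noise extrema.
pick_extrema <- function(x, min_sep, maxima = FALSE, thresh = Inf) {
  s <- if (maxima) -x else x
  n <- length(s)
  cand <- which(s[2:(n - 1)] < s[1:(n - 2)] & s[2:(n - 1)] < s[3:n]) + 1L
  cand <- cand[s[cand] <= thresh]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(s[cand])]
  chosen <- integer(0)
  for (i in cand) {
    if (!length(chosen) || all(abs(chosen - i) >= min_sep)) {
      chosen <- c(chosen, i)
    }
  }
  sort(chosen)
}

#' Detect heel strikes from the heel marker's vertical trajectory
#'
#' A heel strike is the per-cycle local minimum of the vertical heel
#' coordinate. The stride period is estimated from the autocorrelation of
#' the trajectory and candidate minima closer than half that period are
#' suppressed (lowest value wins). Times are reported at sample resolution
#' on the trajectory's clock (first sample = 0 s).
#'
#' @param heel_vertical vertical heel coordinate (mm).
#' @param rate sampling rate (Hz).
#' @return heel-strike times (s), strictly increasing.
#' @export
detect_heel_strikes <- function(heel_vertical, rate) {
  check_positive(rate, "rate")
  per <- estimate_period_samples(heel_vertical, rate)
  if (length(heel_vertical) < 2 * per) {
    stop_invalid("trajectory shorter than two strides")
  }
  # only minima in the lowest part of the trajectory's range qualify, which
  # rejects shallow noise minima on the flat stance plateau
  q01 <- quantile(heel_vertical, 0.01, names = FALSE)
  thresh <- q01 + 0.3 * (median(heel_vertical) - q01)
  idx <- pick_extrema(heel_vertical, min_sep = 0.5 * per, thresh = thresh)
  if (!length(idx)) stop_invalid("no heel strikes found")
  (idx - 1L) / rate
}

#' Detect toe-offs from the heel marker's vertical trajectory
#'
#' A toe-off is the per-cycle maximum of the heel's upward vertical
#' acceleration. The trajectory is low-pass filtered (10 Hz, zero-phase)
#' before double central differencing to stabilise the acceleration peaks;
#' the same half-period separation rule as for heel strikes applies.
#'
#' @inheritParams detect_heel_strikes
#' @param cutoff_hz low-pass cutoff applied before differentiation.
#' @return toe-off times (s), strictly increasing.
#' @export
detect_toe_offs <- function(heel_vertical, rate, cutoff_hz = 10) {
  check_positive(rate, "rate")
  per <- estimate_period_samples(heel_vertical, rate)
  if (length(heel_vertical) < 2 * per) {
    stop_invalid("trajectory shorter than two strides")
  }
  z <- lowpass_zero_phase(heel_vertical, rate, cutoff_hz)
  accel <- central_diff(central_diff(z, rate), rate)
  # guard the filter edge transients
  guard <- min(length(accel) %/% 4L, as.integer(0.1 * rate))
  if (guard > 0) {
    accel[seq_len(guard)] <- -Inf
    accel[(length(accel) - guard + 1L):length(accel)] <- -Inf
  }
  # a toe-off lies between consecutive same-side heel strikes: mask the
  # ground-contact acceleration transient around each heel-strike minimum
  q01 <- quantile(heel_vertical, 0.01, names = FALSE)
  hs_thresh <- q01 + 0.3 * (median(heel_vertical) - q01)
  hs_idx <- pick_extrema(heel_vertical, min_sep = 0.5 * per,
                         thresh = hs_thresh)
  mask <- max(3L, as.integer(0.06 * per))
  for (i in hs_idx) {
    lo <- max(1L, i - mask)
    hi <- min(length(accel), i + mask)
    accel[lo:hi] <- -Inf
  }
  # only acceleration peaks comparable to the per-cycle maxima qualify
  acc_thresh <- 0.25 * quantile(accel[is.finite(accel)], 0.99,
                                names = FALSE)
  idx <- pick_extrema(accel, min_sep = 0.5 * per, maxima = TRUE,
                      thresh = -acc_thresh)
  if (!length(idx)) stop_invalid("no toe-offs found")
  (idx - 1L) / rate
}

#' Detect all gait events from a marker series
#'
#' Convenience wrapper running heel-strike and toe-off detection on both
#' heels of a [new_marker_series()].
#'
#' @param markers a `marker_series` containing `heel_l_z` and `heel_r_z`.
#' @return a [gait_events()] object.
#' @export
detect_gait_events <- function(markers) {
  rate <- markers$rate
  gait_events(
    hs_left = detect_heel_strikes(marker_axis(markers, "heel_l", "z"), rate),
    hs_right = detect_heel_strikes(marker_axis(markers, "heel_r", "z"), rate),
    to_left = detect_toe_offs(marker_axis(markers, "heel_l", "z"), rate),
    to_right = detect_toe_offs(marker_axis(markers, "heel_r", "z"), rate)
  )
}

#' Step width at each heel strike
#'
#' Mediolateral distance between the two heel markers at every heel strike
#' (both sides, in time order). The platform oscillation displaces both feet
#' equally at the instant of contact, so the between-heel difference is
#' unaffected by it.
#'
#' @param left_heel_ml,right_heel_ml mediolateral heel coordinates (mm).
#' @param events a [gait_events()] object.
#' @param rate sampling rate (Hz).
#' @return data frame with `time`, `side` and `step_width` (mm).
#' @export
compute_step_width <- function(left_heel_ml, right_heel_ml, events, rate) {
  check_positive(rate, "rate")
  hs <- rbind(data.frame(time = events$hs_left, side = "left"),
              data.frame(time = events$hs_right, side = "right"))
  hs <- hs[order(hs$time), ]
  idx <- round(hs$time * rate) + 1L
  if (any(idx < 1L) || any(idx > length(left_heel_ml))) {
    stop_invalid("heel-strike outside trajectory span")
  }
  data.frame(time = hs$time, side = hs$side,
             step_width = abs(left_heel_ml[idx] - right_heel_ml[idx]))
}

#' Stride durations from right heel strikes
#'
#' @param hs_right right heel-strike times (s), at least two.
#' @return successive differences (s), one per stride.
#' @export
compute_stride_durations <- function(hs_right) {
  if (length(hs_right) < 2L) stop_invalid("need at least two right heel strikes")
  diff(hs_right)
}

#' Spatiotemporal summary over the last N strides
#'
#' Mean and sample variance (n-1 denominator) of step width and stride
#' duration over the final `window` strides only, mirroring the use of the
#' last 150 strides of a familiarisation period.
#'
#' @param widths per-step widths (mm), time-ordered.
#' @param durations per-stride durations (s), time-ordered.
#' @param window number of most recent strides to keep.
#' @return object of class `spatiotemporal_summary`: means, variances and
#'   `n_strides`.
#' @export
summarize_spatiotemporal <- function(widths, durations, window = 150L) {
  if (window > length(durations)) {
    stop_invalid("window (%d strides) exceeds available strides (%d)",
                 window, length(durations))
  }
  durs <- utils::tail(durations, window)
  # a stride contains two steps; keep the matching tail of the step list
  wids <- utils::tail(widths, 2L * window)
  if (length(wids) < 2L) stop_invalid("too few steps in window")
  structure(list(
    step_width_mean = mean(wids),
    step_width_var = var(wids),
    stride_duration_mean = mean(durs),
    stride_duration_var = var(durs),
    n_strides = length(durs)
  ), class = "spatiotemporal_summary")
}

#' @export
print.spatiotemporal_summary <- function(x, ...) {
  cat(sprintf(paste0("<spatiotemporal_summary> %d strides\n",
                     "  step width  %.1f mm (var %.1f mm^2)\n",
                     "  stride time %.3f s (var %.5f s^2)\n"),
              x$n_strides, x$step_width_mean, x$step_width_var,
              x$stride_duration_mean, x$stride_duration_var))
  invisible(x)
}
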