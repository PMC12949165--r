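#' Delay-embedded state space from thorax mediolateral velocity
#'
#' The velocity series is first time-normalised so each right-heel-strike
#' stride spans exactly `samples_per_stride` points (linear interpolation),
#' then delay-embedded with five time-delayed copies, giving a 6-D state
#' space of `n_strides * samples_per_stride - 5 * delay` rows.
#'
#' @param thorax_ml_velocity mediolateral velocity series (mm/s) on the
#'   marker clock.
#' @param events a [gait_events()] object (right heel strikes used).
#' @param rate sampling rate of the velocity series (Hz).
#' @param n_strides number of complete strides to use.
#' @param samples_per_stride resampled points per stride.
#' @param delay embedding delay in (resampled) samples.
#' @return object of class `state_space`: `matrix` (rows = states, 6
#'   columns), plus the embedding metadata.
#' @export
build_state_space <- function(thorax_ml_velocity, events, rate,
                              n_strides = 150L, samples_per_stride = 100L,
                              delay = 10L) {
  hs <- events$hs_right
  if (length(hs) - 1L < n_strides) {
    stop_invalid("need %d complete strides, have %d", n_strides,
                 length(hs) - 1L)
  }
  t <- (seq_along(thorax_ml_velocity) - 1L) / rate
  segs <- vector("list", n_strides)
  for (k in seq_len(n_strides)) {
    # endpoints at the two heel strikes; stride k contributes
    # samples_per_stride points on [hs_k, hs_{k+1})
    tt <- hs[k] + (hs[k + 1] - hs[k]) *
      (seq_len(samples_per_stride) - 1L) / samples_per_stride
    segs[[k]] <- approx(t, thorax_ml_velocity, xout = tt, rule = 2)$y
  }
  v <- unlist(segs)
  embed_state_space(v, samples_per_stride = samples_per_stride,
                    delay = delay, n_copies = 5L)
}

#' Delay-embed an arbitrary scalar series
#'
#' Lower-level constructor used by [build_state_space()] and directly for
#' non-gait series (e.g. map iterates): columns are the series and
#' `n_copies` delayed copies.
#'
#' @param x scalar series (already time-normalised if applicable).
#' @param samples_per_stride samples per cycle; 1 for map iterates (time is
#'   then measured in iterations).
#' @param delay embedding delay in samples.
#' @param n_copies number of delayed copies (5 gives a 6-D space).
#' @return a `state_space` object.
#' @export
embed_state_space <- function(x, samples_per_stride = 100L, delay = 10L,
                              n_copies = 5L) {
  n <- length(x) - n_copies * delay
  if (n < 2L) stop_invalid("series too short for the requested embedding")
  cols <- lapply(0:n_copies, function(j) x[(1 + j * delay):(n + j * delay)])
  m <- do.call(cbind, cols)
  structure(list(matrix = m, samples_per_stride = samples_per_stride,
                 delay = delay), class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("<state_space> %d x %d (delay %d, %d samples/stride)\n",
              nrow(x$matrix), ncol(x$matrix), x$delay, x$samples_per_stride))
  invisible(x)
}

#' Mean logarithmic divergence curve (Rosenstein's algorithm)
#'
#' For every state, the nearest neighbour outside a temporal exclusion
#' (Theiler) window is found; the curve is the mean over states of the log
#' Euclidean distance between the two trajectories as a function of forward
#' time, expressed in strides.
#'
#' @param space a `state_space`.
#' @param horizon forward horizon in strides.
#' @param theiler temporal exclusion half-window in samples; default half a
#'   stride.
#' @return object of class `divergence_curve`: `time` (strides),
#'   `log_divergence`, and `samples_per_stride`.
#' @export
rosenstein_divergence <- function(space, horizon = 10,
                                  theiler = NULL) {
  m <- space$matrix
  sps <- space$samples_per_stride
  n <- nrow(m)
  if (is.null(theiler)) theiler <- max(1L, as.integer(sps / 2))
  h <- max(1L, as.integer(round(horizon * sps)))
  n_ref <- n - h
  if (n_ref < 2L) stop_invalid("state space shorter than the horizon")
  # nearest neighbour outside the Theiler window, chunked to bound memory
  nn <- integer(n_ref)
  nnd <- rep(Inf, n_ref)
  chunk <- max(1L, as.integer(2e7 / n))
  sq <- rowSums(m^2)
  for (s0 in seq(1L, n_ref, by = chunk)) {
    s1 <- min(s0 + chunk - 1L, n_ref)
    rows <- s0:s1
    d2 <- outer(sq[rows], sq, "+") - 2 * m[rows, , drop = FALSE] %*% t(m)
    for (r in seq_along(rows)) {
      i <- rows[r]
      lo <- max(1L, i - theiler)
      hi <- min(n, i + theiler)
      d2[r, lo:hi] <- Inf
      d2[r, seq.int(n - h + 1L, n)] <- Inf
    }
    # numerically zero distances (recurrences of an identical state) are
    # unusable as neighbours; exclude them with a relative tolerance
    d2[d2 <= 1e-10 * mean(sq)] <- Inf
    nn[rows] <- max.col(-d2, ties.method = "first")
    nnd[rows] <- d2[cbind(seq_along(rows), nn[rows])]
  }
  valid <- is.finite(nnd)
  if (!any(valid)) stop_invalid("all neighbour candidates excluded")
  idx_i <- which(valid)
  idx_j <- nn[valid]
  curve <- numeric(h + 1L)
  for (k in 0:h) {
    dif <- m[idx_i + k, , drop = FALSE] - m[idx_j + k, , drop = FALSE]
    d <- sqrt(rowSums(dif * dif))
    curve[k + 1L] <- mean(log(pmax(d, 1e-300)))
  }
  structure(list(time = (0:h) / sps, log_divergence = curve,
                 samples_per_stride = sps), class = "divergence_curve")
}

#' @export
print.divergence_curve <- function(x, ...) {
  cat(sprintf("<divergence_curve> %d points over %.2f strides\n",
              length(x$time), max(x$time)))
  invisible(x)
}

#' Local divergence exponent from a divergence curve
#'
#' Least-squares slope of the mean log-divergence curve over 0 to 0.5
#' strides (inclusive), the short-term local divergence exponent
#' `lambda_s` (per stride). Larger values indicate greater local
#' instability.
#'
#' @param curve a `divergence_curve`.
#' @param fit_window slope window in strides.
#' @return `lambda_s` (1/stride).
#' @export
estimate_lambda_s <- function(curve, fit_window = c(0, 0.5)) {
  sel <- curve$time >= fit_window[1] - 1e-12 &
    curve$time <= fit_window[2] + 1e-12
  if (sum(sel) < 2L) stop_invalid("divergence curve shorter than fit window")
  x <- curve$time[sel]
  y <- curve$log_divergence[sel]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Thorax mediolateral velocity from a marker series
#'
#' Average of the C7 and both acromion mediolateral positions,
#' differentiated by central differences.
#'
#' @param markers a `marker_series` with `c7`, `acrom_l`, `acrom_r`.
#' @return velocity series (mm/s).
#' @export
thorax_ml_velocity <- function(markers) {
  x <- (marker_axis(markers, "c7", "x") +
          marker_axis(markers, "acrom_l", "x") +
          marker_axis(markers, "acrom_r", "x")) / 3
  central_diff(x, markers$rate)
}
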