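# Map times to gait-cycle percentage (0% = right heel strike), linear
# within each right-HS-to-right-HS interval; NA outside the event span.
cycle_pct_of_time <- function(times, hs_right) {
  idx <- findInterval(times, hs_right)
  pct <- rep(NA_real_, length(times))
  ok <- idx >= 1 & idx < length(hs_right)
  i <- idx[ok]
  pct[ok] <- 100 * (times[ok] - hs_right[i]) /
    (hs_right[i + 1] - hs_right[i])
  pct
}

# Damped-sinusoid MEP waveform template: 8 ms period, 15 ms decay, onset
# 15 ms post-stimulus; returned scaled to unit peak-to-peak amplitude.
mep_waveform <- function(rate) {
  onset <- 0.015
  tau <- seq(0, 0.055, by = 1 / rate)
  w <- ifelse(tau < onset, 0,
              exp(-(tau - onset) / 0.015) * sin(2 * pi * 125 * (tau - onset)))
  w / (max(w) - min(w))
}

#' Generate synthetic EMG with injected motor evoked potentials
#'
#' Each muscle trace is phasic-envelope-modulated band-limited noise (the
#' noise is normalised so its mean rectified value is one, making the local
#' envelope the expected ongoing EMG). Stimulations are scheduled at a right
#' heel strike plus a uniform random delay, with 3-5 strides (configurable)
#' between pulses. At each stimulation a damped-sinusoid MEP whose
#' peak-to-peak amplitude follows `gain(cycle%) x envelope(cycle%)` (times
#' multiplicative noise) is summed into the trace, plus a one-sample
#' stimulation artifact.
#'
#' @param config a [session_config()].
#' @param condition `"steady"` or `"destabilised"`.
#' @param truth ground truth from [generate_gait_kinematics()] (supplies the
#'   right heel-strike times).
#' @param seed RNG seed.
#' @param participant_scale optional multiplicative factor on envelope and
#'   gain amplitudes (between-participant variation).
#' @return list: `emg` (data frame `time` + one column per muscle, uV),
#'   `stimulations` (data frame `stim_time`, `stim_index`, `cycle_pct`),
#'   `true_meps` (matrix stimulations x muscles of injected peak-to-peak
#'   amplitudes, uV), `true_gains` (same shape, the gain-profile values).
#' @export
generate_emg_with_meps <- function(config, condition, truth, seed = 1L,
                                   participant_scale = 1) {
  condition <- match.arg(condition, conditions())
  rate <- config$emg_rate
  hs_r <- truth$hs_right
  if (length(hs_r) < max(config$stim_stride_gap_range) + 1L) {
    stop_invalid("events do not cover the trial: too few right heel strikes")
  }
  dur <- config$trial_duration
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  n <- length(t)
  pct <- cycle_pct_of_time(t, hs_r)
  # outside the event span, reuse the boundary percentage for the envelope
  pct[is.na(pct) & t < hs_r[1]] <- 100 * ((t[is.na(pct) & t < hs_r[1]] -
    hs_r[1]) %% diff(hs_r)[1]) / diff(hs_r)[1]
  pct[is.na(pct)] <- 0

  envs <- config$muscle_envelopes[[condition]]
  gains <- config$mep_gain_profile[[condition]]
  eff <- config$condition_effect

  with_seed(child_seed(seed, paste0("emg-", condition)), {
    # --- stimulation schedule ---
    gaps <- config$stim_stride_gap_range
    stim_idx_stride <- c()
    k <- 1L + sample(gaps[1]:gaps[2], 1L)
    while (k < length(hs_r)) {
      stim_idx_stride <- c(stim_idx_stride, k)
      k <- k + sample(gaps[1]:gaps[2], 1L)
    }
    delay <- runif(length(stim_idx_stride))
    stim_time <- hs_r[stim_idx_stride] +
      delay * (hs_r[stim_idx_stride + 1L] - hs_r[stim_idx_stride])
    stim_index <- round(stim_time * rate) + 1L
    stim_index <- stim_index[stim_index > 0.1 * rate & stim_index < n - 0.1 * rate]
    stim_time <- (stim_index - 1L) / rate
    stim_pct <- cycle_pct_of_time(stim_time, hs_r)
    n_stim <- length(stim_index)

    wav <- mep_waveform(rate)
    bf <- signal::butter(2, c(20, 450) / (rate / 2), type = "pass")
    emg <- data.frame(time = t)
    true_meps <- matrix(0, n_stim, length(config$muscles),
                        dimnames = list(NULL, config$muscles))
    true_gains <- true_meps
    for (m in config$muscles) {
      env <- eval_cyclic_profile(envs[[m]], pct) * participant_scale
      if (config$emg_noise_amp > 0) {
        noise <- as.numeric(signal::filtfilt(bf, rnorm(n)))
        noise <- noise / mean(abs(noise))
        x <- env * noise * config$emg_noise_amp
      } else {
        x <- numeric(n)
      }
      g <- eval_cyclic_profile(gains[[m]], stim_pct) * participant_scale
      if (condition == "destabilised" && m %in% eff$muscles) {
        inwin <- !is.na(stim_pct) & stim_pct >= eff$window[1] &
          stim_pct <= eff$window[2]
        g[inwin] <- g[inwin] * eff$factor
      }
      amp_noise <- if (config$mep_amplitude_noise_sd > 0) {
        pmax(0, rnorm(n_stim, 1, config$mep_amplitude_noise_sd))
      } else rep(1, n_stim)
      env_at_stim <- eval_cyclic_profile(envs[[m]], stim_pct) * participant_scale
      amp <- g * env_at_stim * amp_noise
      for (j in seq_len(n_stim)) {
        i0 <- stim_index[j]
        span <- i0:min(i0 + length(wav) - 1L, n)
        x[span] <- x[span] + amp[j] * wav[seq_along(span)]
      }
      x[stim_index] <- x[stim_index] +
        config$artifact_amplitude * rep_len(c(1, -1), n_stim)
      emg[[m]] <- x
      true_meps[, m] <- amp
      true_gains[, m] <- g
    }
    list(emg = emg,
         stimulations = data.frame(stim_time = stim_time,
                                   stim_index = stim_index,
                                   cycle_pct = stim_pct),
         true_meps = true_meps,
         true_gains = true_gains)
  })
}

#' Generate per-stimulation coil displacement with a controlled exceedance rate
#'
#' Baseline displacements stay strictly inside the exclusion thresholds
#' (vertical <= 4.5 mm, horizontal <= 9 mm); a `coil_exceedance_rate`
#' fraction of stimulations is pushed beyond a threshold (vertical > 5 mm or
#' horizontal > 10 mm, chosen with equal probability).
#'
#' @param config a [session_config()].
#' @param n_stimulations number of stimulations.
#' @param seed RNG seed.
#' @return data frame with columns `coil_vertical`, `coil_horizontal` (mm)
#'   and the logical ground-truth flag `exceeds`.
#' @export
generate_coil_displacement <- function(config, n_stimulations, seed = 1L) {
  rate <- config$coil_exceedance_rate
  if (rate < 0 || rate > 1) stop_invalid("coil_exceedance_rate must be in [0, 1]")
  with_seed(child_seed(seed, "coil"), {
    exceeds <- runif(n_stimulations) < rate
    vert <- runif(n_stimulations, 0.1, 4.5)
    horiz <- runif(n_stimulations, 0.2, 9.0)
    which_axis <- runif(n_stimulations) < 0.5
    vert[exceeds & which_axis] <- 5 + stats::rexp(sum(exceeds & which_axis), 1)
    horiz[exceeds & !which_axis] <- 10 + stats::rexp(sum(exceeds & !which_axis), 0.5)
    data.frame(coil_vertical = vert, coil_horizontal = horiz,
               exceeds = exceeds)
  })
}

#' Simulate stimulation-level outcome samples for paired condition designs
#'
#' Lightweight generator of sparse per-stimulation outcome samples (e.g.
#' MEP gain) for a paired two-condition group study, used to calibrate the
#' cluster-based permutation test at scale without synthesising full
#' sessions. Each participant gets a multiplicative random effect and
#' log-normal sampling noise around a common cyclic profile; the second
#' condition's profile is multiplied by `effect_factor` inside
#' `effect_window` (% of cycle), so `effect_factor = 1` gives exchangeable
#' null conditions.
#'
#' @param n_participants participants.
#' @param n_stim stimulations per participant per condition.
#' @param effect_window `c(lo, hi)` in % of the gait cycle.
#' @param effect_factor multiplicative condition effect inside the window
#'   (1 = null).
#' @param noise_sd log-normal sampling noise SD.
#' @param participant_sd log-normal between-participant SD.
#' @param baseline profile baseline level.
#' @param seed RNG seed.
#' @return list with elements `a` and `b`: per-participant lists of data
#'   frames (`cycle_pct`, `value`), condition `b` carrying the effect.
#' @export
simulate_outcome_samples <- function(n_participants = 15, n_stim = 200,
                                     effect_window = c(55, 80),
                                     effect_factor = 1, noise_sd = 0.4,
                                     participant_sd = 0.2, baseline = 3,
                                     seed = 1L) {
  profile <- function(pct) baseline * (1 + 0.3 * sin(2 * pi * pct / 100))
  with_seed(seed, {
    draw <- function(scale, factor) {
      pct <- runif(n_stim, 0, 100)
      mu <- profile(pct)
      inwin <- pct >= effect_window[1] & pct <= effect_window[2]
      mu[inwin] <- mu[inwin] * factor
      data.frame(cycle_pct = pct,
                 value = scale * mu * exp(rnorm(n_stim, 0, noise_sd)))
    }
    a <- vector("list", n_participants)
    b <- vector("list", n_participants)
    for (p in seq_len(n_participants)) {
      scale <- exp(rnorm(1, 0, participant_sd))
      a[[p]] <- draw(scale, 1)
      b[[p]] <- draw(scale, effect_factor)
    }
    list(a = a, b = b)
  })
}

#' Simulate the motor-threshold staircase
#'
#' Replays the threshold-hunting protocol: start at 35% of maximal
#' stimulator output; increase in 5% steps until an MEP is observed in at
#' least 5 of 10 stimulations (or the ceiling is reached, terminating the
#' session); then decrease in 2% steps until the criterion is lost; finally
#' increase in 1% steps until the lowest intensity that consistently evokes
#' an MEP is found. The experimental test intensity is 110% of threshold.
#'
#' @param recruitment function mapping intensity (% stimulator output) to
#'   the probability of observing an MEP on a single stimulation; must be
#'   monotone non-decreasing.
#' @param seed RNG seed (used for the 10-trial blocks when probabilities are
#'   not 0/1).
#' @param start starting intensity (%); also the decrement floor.
#' @param ceiling maximum tolerated intensity (%).
#' @param n_trials stimulations per block.
#' @param criterion MEPs out of `n_trials` required.
#' @return list with `threshold`, `test_intensity` (110% of threshold) and
#'   `status` (`"ok"` or `"terminated"`).
#' @export
simulate_threshold_hunt <- function(recruitment, seed = 1L, start = 35,
                                    ceiling = 100, n_trials = 10L,
                                    criterion = 5L) {
  stopifnot(is.function(recruitment))
  with_seed(child_seed(seed, "staircase"), {
    evokes <- function(intensity) {
      p <- recruitment(intensity)
      if (p < 0 || p > 1) stop_invalid("recruitment must return a probability")
      hits <- if (p %in% c(0, 1)) p * n_trials else rbinom(1, n_trials, p)
      hits >= criterion
    }
    i <- start
    while (!evokes(i)) {
      i <- i + 5
      if (i > ceiling) {
        return(list(threshold = NA_real_, test_intensity = NA_real_,
                    status = "terminated"))
      }
    }
    while (i - 2 >= start && evokes(i - 2)) i <- i - 2
    if (i - 2 >= start) {
      # criterion lost at i - 2; climb back in 1% steps
      i <- i - 2
      while (!evokes(i)) i <- i + 1
    }
    list(threshold = i, test_intensity = 1.1 * i, status = "ok")
  })
}
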