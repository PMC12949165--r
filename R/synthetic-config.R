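#' Configuration for a synthetic treadmill-gait session
#'
#' Bundles every tunable of the synthetic-session generator. Most parameters
#' are given per condition as a named length-2 vector
#' `c(steady = ..., destabilised = ...)`; scalars are recycled to both
#' conditions. Defaults emulate the study protocol this package targets:
#' 4.0 km/h belt speed, 100 mm peak-to-peak pseudorandom mediolateral
#' platform oscillation in the destabilised condition, 20-min trials,
#' stimulations every 3-5 strides at a random delay after right heel strike.
#'
#' @param n_participants number of participants to simulate.
#' @param trial_duration trial length in seconds.
#' @param marker_rate motion-capture sampling rate (Hz).
#' @param emg_rate EMG sampling rate (Hz).
#' @param belt_speed treadmill belt speed (km/h); only used for provenance.
#' @param perturbation_peak_to_peak peak-to-peak amplitude (mm) of the
#'   mediolateral platform oscillation, per condition.
#' @param stride_duration_mean,stride_duration_sd stride-time moments (s),
#'   per condition.
#' @param step_width_mean,step_width_sd nominal step width (mm) and extra
#'   placement variability (mm) folded into the placement residual.
#' @param beta_position,beta_velocity foot-placement-control coefficients at
#'   the placement instant (mm per mm, mm per mm/s), per condition.
#' @param epsilon_sd residual SD (mm) of the foot-placement law.
#' @param sway_amplitude pelvis mediolateral sway amplitude (mm).
#' @param sway_noise_sd SD (mm) of the low-frequency pelvis noise.
#' @param thorax_noise_sd SD (mm) of the low-frequency thorax noise.
#' @param perturbation_coupling fraction of the platform displacement that
#'   appears in lab-frame pelvis/thorax motion.
#' @param marker_noise_sd white measurement noise on individual markers (mm).
#' @param muscles character vector of muscle names to simulate.
#' @param muscle_envelopes per-condition, per-muscle phasic activity bumps;
#'   `NULL` uses built-in templates for the seven study muscles. Each muscle
#'   entry is a data frame with columns `centre` (% cycle), `width`
#'   (% cycle), `amplitude` (uV) plus an attribute-free `baseline` column.
#' @param mep_gain_profile per-condition, per-muscle MEP-gain description
#'   (`baseline` gain plus optional bump columns as for envelopes); `NULL`
#'   uses built-in templates.
#' @param condition_effect injected condition difference: a list with
#'   `muscles`, `window` (c(lo, hi) in % cycle) and `factor`; the
#'   destabilised MEP gain is multiplied by `factor` inside the window.
#' @param emg_noise_amp multiplier on the envelope-modulated EMG noise
#'   (0 gives a noise-free background).
#' @param mep_amplitude_noise_sd relative SD of multiplicative MEP-amplitude
#'   noise.
#' @param artifact_amplitude stimulation-artifact spike amplitude (uV).
#' @param stim_stride_gap_range integer range of strides between successive
#'   stimulations.
#' @param coil_exceedance_rate probability that a stimulation exceeds the
#'   coil-displacement exclusion thresholds.
#' @param participant_sd between-participant log-normal SD applied to
#'   envelope and gain amplitudes.
#' @param rng_seed root seed; all child streams derive from it.
#'
#' @return An object of class `session_config` (a validated list).
#' @export
session_config <- function(n_participants = 15,
                           trial_duration = 1200,
                           marker_rate = 100,
                           emg_rate = 2000,
                           belt_speed = 4.0,
                           perturbation_peak_to_peak = c(steady = 0, destabilised = 100),
                           stride_duration_mean = c(steady = 1.10, destabilised = 1.05),
                           stride_duration_sd = c(steady = 0.020, destabilised = 0.045),
                           step_width_mean = c(steady = 100, destabilised = 130),
                           step_width_sd = c(steady = 0, destabilised = 0),
                           beta_position = c(steady = 0.85, destabilised = 1.00),
                           beta_velocity = c(steady = 0.25, destabilised = 0.30),
                           epsilon_sd = c(steady = 6, destabilised = 10),
                           sway_amplitude = c(steady = 12, destabilised = 16),
                           sway_noise_sd = c(steady = 4, destabilised = 8),
                           thorax_noise_sd = c(steady = 3, destabilised = 7),
                           perturbation_coupling = 0.35,
                           marker_noise_sd = 0.3,
                           muscles = c("adductor_magnus", "biceps_femoris",
                                       "gluteus_medius", "rectus_femoris",
                                       "tibialis_anterior",
                                       "gastrocnemius_medialis",
                                       "gastrocnemius_lateralis"),
                           muscle_envelopes = NULL,
                           mep_gain_profile = NULL,
                           condition_effect = list(
                             muscles = c("rectus_femoris", "biceps_femoris"),
                             window = c(55, 80), factor = 1.5),
                           emg_noise_amp = 1,
                           mep_amplitude_noise_sd = 0.15,
                           artifact_amplitude = 2000,
                           stim_stride_gap_range = c(3L, 5L),
                           coil_exceedance_rate = 0.02,
                           participant_sd = 0.15,
                           rng_seed = 1L) {
  cfg <- list(
    n_participants = n_participants,
    trial_duration = trial_duration,
    marker_rate = marker_rate,
    emg_rate = emg_rate,
    belt_speed = belt_speed,
    perturbation_peak_to_peak = per_condition(perturbation_peak_to_peak),
    stride_duration_mean = per_condition(stride_duration_mean),
    stride_duration_sd = per_condition(stride_duration_sd),
    step_width_mean = per_condition(step_width_mean),
    step_width_sd = per_condition(step_width_sd),
    beta_position = per_condition(beta_position),
    beta_velocity = per_condition(beta_velocity),
    epsilon_sd = per_condition(epsilon_sd),
    sway_amplitude = per_condition(sway_amplitude),
    sway_noise_sd = per_condition(sway_noise_sd),
    thorax_noise_sd = per_condition(thorax_noise_sd),
    perturbation_coupling = perturbation_coupling,
    marker_noise_sd = marker_noise_sd,
    muscles = muscles,
    muscle_envelopes = muscle_envelopes %||% default_muscle_envelopes(muscles),
    mep_gain_profile = mep_gain_profile %||% default_gain_profiles(muscles),
    condition_effect = condition_effect,
    emg_noise_amp = emg_noise_amp,
    mep_amplitude_noise_sd = mep_amplitude_noise_sd,
    artifact_amplitude = artifact_amplitude,
    stim_stride_gap_range = as.integer(stim_stride_gap_range),
    coil_exceedance_rate = coil_exceedance_rate,
    participant_sd = participant_sd,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "session_config"
  validate_session_config(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

conditions <- function() c("steady", "destabilised")

# Recycle a scalar to both conditions; keep named length-2 vectors as-is.
per_condition <- function(x) {
  if (length(x) == 1L) x <- c(steady = unname(x), destabilised = unname(x))
  if (is.null(names(x)) && length(x) == 2L) names(x) <- conditions()
  if (!all(conditions() %in% names(x))) {
    stop_invalid("per-condition parameters need names 'steady' and 'destabilised'")
  }
  x[conditions()]
}

cond_par <- function(config, field, condition) {
  unname(config[[field]][[condition]])
}

validate_session_config <- function(cfg) {
  check_positive(cfg$trial_duration, "trial_duration")
  check_positive(cfg$marker_rate, "marker_rate")
  check_positive(cfg$emg_rate, "emg_rate")
  check_positive(cfg$n_participants, "n_participants")
  for (f in c("stride_duration_sd", "step_width_sd", "epsilon_sd",
              "sway_noise_sd", "thorax_noise_sd")) {
    if (any(cfg[[f]] < 0)) stop_invalid("`%s` must be non-negative", f)
  }
  if (any(cfg$perturbation_peak_to_peak < 0)) {
    stop_invalid("`perturbation_peak_to_peak` must be non-negative")
  }
  if (any(cfg$stride_duration_mean <= 0)) {
    stop_invalid("`stride_duration_mean` must be positive")
  }
  g <- cfg$stim_stride_gap_range
  if (length(g) != 2L || g[1] > g[2] || g[1] < 1L || g[2] > 20L) {
    stop_invalid("`stim_stride_gap_range` must lie within [1, 20]")
  }
  if (cfg$coil_exceedance_rate < 0 || cfg$coil_exceedance_rate > 1) {
    stop_invalid("`coil_exceedance_rate` must be in [0, 1]")
  }
  invisible(cfg)
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>\n")
  cat(sprintf("  participants: %d, trial: %gs, marker %g Hz / EMG %g Hz\n",
              x$n_participants, x$trial_duration, x$marker_rate, x$emg_rate))
  cat(sprintf("  perturbation p2p: steady %g mm, destabilised %g mm\n",
              x$perturbation_peak_to_peak[["steady"]],
              x$perturbation_peak_to_peak[["destabilised"]]))
  cat(sprintf("  stride: %.3f/%.3f s, step width: %g/%g mm (steady/destab)\n",
              x$stride_duration_mean[["steady"]],
              x$stride_duration_mean[["destabilised"]],
              x$step_width_mean[["steady"]],
              x$step_width_mean[["destabilised"]]))
  cat(sprintf("  muscles: %s\n", paste(x$muscles, collapse = ", ")))
  invisible(x)
}

# Phasic activity templates loosely following typical gait EMG timing
# (0% = right heel strike; muscles are on the right leg).
default_muscle_envelopes <- function(muscles) {
  bump <- function(centre, width, amplitude) {
    data.frame(centre = centre, width = width, amplitude = amplitude)
  }
  base <- list(
    adductor_magnus = bump(c(5, 90), c(8, 8), c(35, 25)),
    biceps_femoris = bump(c(92, 8), c(7, 8), c(45, 30)),
    gluteus_medius = bump(c(12, 95), c(10, 6), c(50, 20)),
    rectus_femoris = bump(c(8, 62), c(8, 6), c(40, 20)),
    tibialis_anterior = bump(c(2, 68), c(6, 14), c(55, 35)),
    gastrocnemius_medialis = bump(40, 10, 70),
    gastrocnemius_lateralis = bump(40, 10, 55)
  )
  baseline <- c(adductor_magnus = 8, biceps_femoris = 8, gluteus_medius = 9,
                rectus_femoris = 8, tibialis_anterior = 10,
                gastrocnemius_medialis = 7, gastrocnemius_lateralis = 7)
  out <- lapply(muscles, function(m) {
    env <- base[[m]] %||% bump(50, 12, 40)
    attr(env, "baseline") <- unname(baseline[m] %||% 8)
    if (is.na(attr(env, "baseline"))) attr(env, "baseline") <- 8
    env
  })
  names(out) <- muscles
  list(steady = out, destabilised = lapply(out, function(env) {
    env$amplitude <- env$amplitude * 1.2  # generally higher drive when destabilised
    env
  }))
}

# MEP gain (dimensionless) over the cycle: baseline plus mild modulation.
default_gain_profiles <- function(muscles) {
  prof <- function(baseline, centre = 50, width = 20, amplitude = 0) {
    df <- data.frame(centre = centre, width = width, amplitude = amplitude)
    attr(df, "baseline") <- baseline
    df
  }
  out <- lapply(muscles, function(m) prof(baseline = 3, centre = 30,
                                          width = 15, amplitude = 1))
  names(out) <- muscles
  list(steady = out, destabilised = out)
}

# Evaluate a bump table (+ baseline attribute) at gait-cycle percentages,
# using a circular (von Mises shaped) bump so 0% and 100% coincide.
eval_cyclic_profile <- function(profile, pct) {
  base <- attr(profile, "baseline") %||% 0
  y <- rep(base, length(pct))
  if (!is.null(profile) && nrow(profile) > 0) {
    for (i in seq_len(nrow(profile))) {
      w_rad <- 2 * pi * profile$width[i] / 100
      kap <- 1 / w_rad^2
      th <- 2 * pi * (pct - profile$centre[i]) / 100
      y <- y + profile$amplitude[i] * exp(kap * (cos(th) - 1))
    }
  }
  y
}
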