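#' Analysis configuration
#'
#' Fixed constants of the analysis pipeline, with the protocol values as
#' defaults: 0.5% cyclic grid, von Mises concentration 60 (Gaussian sigma
#' 2% equivalent), alpha 0.05, 1000 permutations, coil exclusion at 5 mm
#' vertical / 10 mm horizontal, at least 100 surviving stimulations per
#' condition, divergence-exponent fit over 0-0.5 strides, spatiotemporal
#' statistics over the last 150 strides.
#'
#' @param grid_resolution cyclic grid spacing (% of cycle).
#' @param sigma_pct Gaussian-equivalent kernel width (% of cycle).
#' @param kappa von Mises concentration; default derived from `sigma_pct`
#'   and rounded to the nearest ten.
#' @param alpha significance level.
#' @param n_permutations permutations for the cluster test.
#' @param mode group-averaging / test mode (`"weighted"` or
#'   `"unweighted"`).
#' @param coil_vertical_mm,coil_horizontal_mm coil exclusion thresholds.
#' @param min_stim_per_condition participant-inclusion minimum.
#' @param lambda_fit_window slope window for `lambda_s` (strides).
#' @param lambda_n_strides strides used for the state space (capped at the
#'   available count).
#' @param samples_per_stride,embedding_delay state-space construction.
#' @param stride_window strides for the spatiotemporal summary (capped at
#'   the available count).
#' @param seed root analysis seed (permutations).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(grid_resolution = 0.5, sigma_pct = 2,
                            kappa = kappa_from_sigma(sigma_pct, TRUE),
                            alpha = 0.05, n_permutations = 1000L,
                            mode = c("weighted", "unweighted"),
                            coil_vertical_mm = 5, coil_horizontal_mm = 10,
                            min_stim_per_condition = 100L,
                            lambda_fit_window = c(0, 0.5),
                            lambda_n_strides = 150L,
                            samples_per_stride = 100L,
                            embedding_delay = 10L,
                            stride_window = 150L,
                            seed = 1L) {
  mode <- match.arg(mode)
  cfg <- list(grid_resolution = grid_resolution, sigma_pct = sigma_pct,
              kappa = kappa, alpha = alpha,
              n_permutations = as.integer(n_permutations), mode = mode,
              coil_vertical_mm = coil_vertical_mm,
              coil_horizontal_mm = coil_horizontal_mm,
              min_stim_per_condition = as.integer(min_stim_per_condition),
              lambda_fit_window = lambda_fit_window,
              lambda_n_strides = as.integer(lambda_n_strides),
              samples_per_stride = as.integer(samples_per_stride),
              embedding_delay = as.integer(embedding_delay),
              stride_window = as.integer(stride_window),
              seed = as.integer(seed))
  check_positive(cfg$grid_resolution, "grid_resolution")
  check_positive(cfg$kappa, "kappa")
  check_positive(cfg$coil_vertical_mm, "coil_vertical_mm")
  check_positive(cfg$coil_horizontal_mm, "coil_horizontal_mm")
  if (abs(100 / cfg$grid_resolution - round(100 / cfg$grid_resolution)) > 1e-9) {
    stop_invalid("grid_resolution must divide 100")
  }
  structure(cfg, class = "analysis_config")
}

#' Simulate one participant's full session (both conditions)
#'
#' Kinematics, perturbation, EMG with MEPs, stimulation schedule and coil
#' displacements for the steady and destabilised conditions, with all
#' ground truth retained.
#'
#' @param config a [session_config()].
#' @param participant participant index (drives the RNG stream and the
#'   between-participant scaling).
#' @param seed root seed; defaults to the config's.
#' @return list with one entry per condition; each holds `markers`,
#'   `perturbation`, `truth`, `emg`, `stimulations`, `true_meps`,
#'   `true_gains`, `coil`.
#' @export
simulate_session <- function(config, participant = 1L, seed = NULL) {
  seed <- seed %||% config$rng_seed
  pseed <- child_seed(seed, paste0("participant-", participant))
  scale <- if (config$participant_sd > 0) {
    with_seed(child_seed(pseed, "scale"),
              exp(rnorm(1, 0, config$participant_sd)))
  } else 1
  out <- list()
  for (cond in conditions()) {
    kin <- generate_gait_kinematics(config, cond, seed = pseed)
    emg <- generate_emg_with_meps(config, cond, kin$truth, seed = pseed,
                                  participant_scale = scale)
    coil <- generate_coil_displacement(config, nrow(emg$stimulations),
                                       seed = child_seed(pseed, cond))
    out[[cond]] <- c(kin, emg, list(coil = coil))
  }
  out
}

#' Analyse one participant-condition trial
#'
#' Runs the single-trial part of the pipeline on one condition's data:
#' gait-event detection, spatiotemporal summary, local divergence exponent,
#' foot-placement fit, stimulation-record extraction and exclusion rules.
#'
#' @param session_cond list with `markers` (a `marker_series`), `emg`
#'   (data frame `time` + muscle columns), `stimulations` (data frame with
#'   `stim_index`), `coil` (coil-displacement data frame or `NULL`) and
#'   `perturbation` (data frame with `displacement`).
#' @param analysis an [analysis_config()].
#' @return list with `events`, `spatiotemporal`, `lambda_s`,
#'   `divergence_curve`, `foot_placement`, `records`, `n_surviving`,
#'   `participant_included`.
#' @export
analyze_trial <- function(session_cond, analysis = analysis_config()) {
  markers <- session_cond$markers
  rate <- markers$rate
  events <- detect_gait_events(markers)
  durations <- compute_stride_durations(events$hs_right)
  widths <- compute_step_width(marker_axis(markers, "heel_l", "x"),
                               marker_axis(markers, "heel_r", "x"),
                               events, rate)
  window <- min(analysis$stride_window, length(durations))
  spatio <- summarize_spatiotemporal(widths$step_width, durations, window)
  n_str <- min(analysis$lambda_n_strides, length(events$hs_right) - 1L)
  space <- build_state_space(thorax_ml_velocity(markers), events, rate,
                             n_strides = n_str,
                             samples_per_stride = analysis$samples_per_stride,
                             delay = analysis$embedding_delay)
  curve <- rosenstein_divergence(space)
  lambda_s <- estimate_lambda_s(curve, analysis$lambda_fit_window)
  cycles <- extract_step_cycles(markers, events,
                                session_cond$perturbation$displacement)
  fp_fit <- fit_foot_placement(cycles)
  records <- extract_stimulation_records(session_cond$emg,
                                         session_cond$stimulations$stim_index,
                                         rate = attr_emg_rate(session_cond),
                                         hs_right = events$hs_right,
                                         coil = session_cond$coil)
  excl <- apply_exclusions(records, analysis$coil_vertical_mm,
                           analysis$coil_horizontal_mm,
                           analysis$min_stim_per_condition)
  list(events = events, spatiotemporal = spatio, lambda_s = lambda_s,
       divergence_curve = curve, foot_placement = fp_fit,
       records = excl$records, n_surviving = excl$n_surviving,
       participant_included = excl$participant_included)
}

attr_emg_rate <- function(session_cond) {
  dt <- diff(session_cond$emg$time[1:2])
  round(1 / dt)
}

#' Run the full analysis pipeline on simulated sessions
#'
#' Simulates `config$n_participants` sessions and runs the complete
#' analysis per participant-condition (event detection, spatiotemporal
#' metrics, local divergence exponent, foot-placement fit, MEP extraction
#' and exclusions), then the group level: von Mises smoothing of ongoing
#' EMG / absolute MEP / MEP gain per muscle, cyclic cluster-based
#' permutation tests between conditions, and paired t-tests for the scalar
#' gait outcomes. Deterministic given `config` and the analysis seed.
#'
#' @param config a [session_config()].
#' @param analysis an [analysis_config()].
#' @param outcomes which stimulation outcomes to smooth and test.
#' @param muscles subset of muscles to test at group level (default all in
#'   `config`).
#' @param progress emit per-stage messages.
#' @return object of class `results_bundle`.
#' @export
run_pipeline <- function(config, analysis = analysis_config(),
                         outcomes = c("ongoing_emg", "absolute_mep",
                                      "mep_gain"),
                         muscles = NULL, progress = FALSE) {
  validate_session_config(config)
  muscles <- muscles %||% config$muscles
  say <- function(...) if (progress) message(sprintf(...))
  participants <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    say("participant %d/%d: simulating", p, config$n_participants)
    sess <- simulate_session(config, p)
    res <- list()
    for (cond in conditions()) {
      say("participant %d: analysing %s", p, cond)
      res[[cond]] <- tryCatch(
        analyze_trial(sess[[cond]], analysis),
        error = function(e) {
          stop_invalid("participant %d, condition %s: %s", p, cond,
                       conditionMessage(e))
        })
    }
    participants[[p]] <- res
  }
  grid <- cyclic_grid(analysis$grid_resolution)
  say("group-level cluster tests")
  included <- vapply(participants, function(r) {
    r$steady$participant_included && r$destabilised$participant_included
  }, logical(1))
  if (sum(included) < 2L) {
    stop_invalid(paste0("fewer than two participants meet the minimum of %d ",
                        "surviving stimulations per condition"),
                 analysis$min_stim_per_condition)
  }
  cluster_results <- list()
  for (m in muscles) {
    for (oc in outcomes) {
      pull <- function(cond) lapply(participants[included], function(r) {
        rec <- r[[cond]]$records
        rec <- rec[rec$muscle == m & rec$included & !is.na(rec[[oc]]), ]
        data.frame(cycle_pct = rec$cycle_pct, value = rec[[oc]])
      })
      key <- paste(m, oc, sep = ".")
      cluster_results[[key]] <- cluster_permutation_test_records(
        pull("destabilised"), pull("steady"), grid = grid,
        kappa = analysis$kappa, sigma_pct = analysis$sigma_pct,
        mode = analysis$mode, n_permutations = analysis$n_permutations,
        alpha = analysis$alpha,
        seed = child_seed(analysis$seed, key))
    }
  }
  scalar <- function(f) {
    a <- vapply(participants, function(r) f(r$destabilised), numeric(1))
    b <- vapply(participants, function(r) f(r$steady), numeric(1))
    paired_t_scalar(a, b)
  }
  scalar_tests <- list(
    step_width_mean = scalar(function(r) r$spatiotemporal$step_width_mean),
    step_width_var = scalar(function(r) r$spatiotemporal$step_width_var),
    stride_duration_mean = scalar(function(r) r$spatiotemporal$stride_duration_mean),
    stride_duration_var = scalar(function(r) r$spatiotemporal$stride_duration_var),
    lambda_s = scalar(function(r) r$lambda_s),
    fp_error = scalar(function(r) r$foot_placement$fp_error)
  )
  structure(list(
    participants = participants,
    included = included,
    cluster_results = cluster_results,
    scalar_tests = scalar_tests,
    provenance = list(
      config_hash = rlang::hash(list(config, analysis)),
      seed = analysis$seed,
      version = as.character(utils::packageVersion("gaitmep")),
      timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  cat(sprintf("<results_bundle> %d participants (%d included), %d cluster tests\n",
              length(x$participants), sum(x$included),
              length(x$cluster_results)))
  for (nm in names(x$scalar_tests)) {
    st <- x$scalar_tests[[nm]]
    cat(sprintf("  %s: diff %.4g, t(%d) = %.2f, p = %.4g\n", nm,
                st$mean_difference, st$df, st$t, st$p_value))
  }
  invisible(x)
}
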