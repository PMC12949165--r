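#' Zero-phase band-pass filter for surface EMG
#'
#' Second-order Butterworth band-pass (20-500 Hz by default) applied forward
#' and backward (`filtfilt`), i.e. a bi-directional second-order design with
#' zero phase lag and an effective fourth-order magnitude response. DC is
#' removed by the high-pass edge.
#'
#' @param raw_emg raw EMG trace (uV).
#' @param rate sampling rate (Hz); must exceed 1000 Hz so the 500 Hz edge is
#'   below Nyquist.
#' @param band filter pass band (Hz).
#' @return filtered trace (uV).
#' @export
bandpass_filter <- function(raw_emg, rate, band = c(20, 500)) {
  check_positive(rate, "rate")
  if (rate <= 1000) {
    stop_invalid("EMG rate must exceed 1000 Hz for a 500 Hz pass-band edge")
  }
  bf <- signal::butter(2, band / (rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, raw_emg))
}

ms_to_samples <- function(ms, rate) as.integer(round(ms / 1000 * rate))

#' Ongoing EMG around a stimulation
#'
#' Mean rectified filtered EMG from 20 ms before to 10 ms after the
#' stimulation (window endpoints inclusive), with the single sample at the
#' stimulation instant excluded so the stimulation artifact cannot
#' contribute.
#'
#' @param filtered band-pass-filtered EMG trace (uV).
#' @param stim_index sample index (1-based) of the stimulation.
#' @param rate sampling rate (Hz).
#' @return ongoing EMG (uV).
#' @export
compute_ongoing_emg <- function(filtered, stim_index, rate) {
  lo <- stim_index - ms_to_samples(20, rate)
  hi <- stim_index + ms_to_samples(10, rate)
  if (lo < 1L || hi > length(filtered)) {
    stop_invalid("ongoing-EMG window outside the series")
  }
  idx <- setdiff(lo:hi, stim_index)
  mean(abs(filtered[idx]))
}

#' Absolute MEP amplitude
#'
#' Peak-to-peak amplitude of the filtered EMG within 10-60 ms
#' post-stimulation (endpoints inclusive).
#'
#' @inheritParams compute_ongoing_emg
#' @return peak-to-peak amplitude (uV).
#' @export
compute_absolute_mep <- function(filtered, stim_index, rate) {
  lo <- stim_index + ms_to_samples(10, rate)
  hi <- stim_index + ms_to_samples(60, rate)
  if (lo < 1L || hi > length(filtered)) {
    stop_invalid("MEP window outside the series")
  }
  w <- filtered[lo:hi]
  max(w) - min(w)
}

#' MEP gain
#'
#' Absolute MEP amplitude divided by the ongoing EMG. A zero ongoing EMG
#' yields `NA` (undefined gain, record retained) rather than an infinite
#' value.
#'
#' @param absolute_mep peak-to-peak MEP amplitude (uV).
#' @param ongoing_emg ongoing EMG (uV).
#' @return dimensionless gain, or `NA` where `ongoing_emg` is zero.
#' @export
compute_mep_gain <- function(absolute_mep, ongoing_emg) {
  ifelse(ongoing_emg > 0, absolute_mep / ongoing_emg, NA_real_)
}

# Least-squares rigid transform (rotation + translation, Kabsch) mapping
# points A (n x 3) onto B (n x 3).
rigid_transform <- function(A, B) {
  if (nrow(A) < 3L) stop_invalid("need at least 3 markers for a rigid fit")
  ca <- colMeans(A)
  cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = cb - as.numeric(R %*% ca))
}

apply_rigid <- function(tr, p) as.numeric(tr$R %*% p) + tr$t

#' Relative coil displacement from helmet and head marker sets
#'
#' A virtual marker (the coil target, measured once in a static
#' calibration) is predicted at the stimulation instant from two
#' independent rigid marker sets: the helmet's rigid markers and the head
#' markers. The displacement of the helmet relative to the head is the
#' difference between the two predictions; its absolute vertical component
#' and the Euclidean norm of the two horizontal components are reported.
#'
#' @param calibration list with matrices `helmet` and `head` (n x 3, mm,
#'   rows = markers) and the virtual-marker position `virtual` (length-3).
#' @param helmet_markers,head_markers the same marker sets at the
#'   stimulation instant (n x 3, same row order as calibration).
#' @param vertical_axis which column is vertical (default 3).
#' @return named vector `c(vertical =, horizontal =)` in mm.
#' @export
compute_virtual_marker_displacement <- function(calibration, helmet_markers,
                                                head_markers,
                                                vertical_axis = 3L) {
  check_rigid_set <- function(m, name) {
    if (!is.matrix(m) || nrow(m) < 3L || ncol(m) != 3L || any(!is.finite(m))) {
      stop_invalid("`%s` must be a finite n x 3 matrix with n >= 3", name)
    }
    if (qr(sweep(m, 2, colMeans(m)))$rank < 2L) {
      stop_invalid("`%s` markers are collinear", name)
    }
  }
  check_rigid_set(calibration$helmet, "calibration$helmet")
  check_rigid_set(calibration$head, "calibration$head")
  check_rigid_set(helmet_markers, "helmet_markers")
  check_rigid_set(head_markers, "head_markers")
  tr_helmet <- rigid_transform(calibration$helmet, helmet_markers)
  tr_head <- rigid_transform(calibration$head, head_markers)
  v_helmet <- apply_rigid(tr_helmet, calibration$virtual)
  v_head <- apply_rigid(tr_head, calibration$virtual)
  dvec <- v_head - v_helmet
  horiz <- sqrt(sum(dvec[-vertical_axis]^2))
  c(vertical = abs(dvec[vertical_axis]), horizontal = horiz)
}

#' Gait-cycle percentage of a stimulation
#'
#' Position of a stimulation within its right-heel-strike-to-right-heel-
#' strike interval, as a percentage in `[0, 100)`.
#'
#' @param stim_time stimulation times (s).
#' @param hs_right right heel-strike times (s).
#' @return percentages; stimulations outside the event span yield `NA` with
#'   a warning.
#' @export
assign_cycle_percentage <- function(stim_time, hs_right) {
  pct <- cycle_pct_of_time(stim_time, hs_right)
  if (anyNA(pct)) {
    warning(sprintf("%d stimulation(s) outside the heel-strike span excluded",
                    sum(is.na(pct))), call. = FALSE)
  }
  pct
}

#' Build per-stimulation records from EMG and events
#'
#' Filters every muscle channel once, then extracts ongoing EMG, absolute
#' MEP and MEP gain for each stimulation, attaches the gait-cycle
#' percentage and coil displacement, and returns one row per stimulation
#' per muscle.
#'
#' @param emg data frame: `time` plus one column per muscle (uV) at `rate`.
#' @param stim_index 1-based stimulation sample indices.
#' @param rate EMG sampling rate (Hz).
#' @param hs_right right heel-strike times (s).
#' @param coil optional data frame with `coil_vertical`/`coil_horizontal`
#'   (mm, one row per stimulation); zeros if omitted.
#' @return data frame of class `stimulation_records`: `stim`, `stim_time`,
#'   `cycle_pct`, `coil_vertical`, `coil_horizontal`, `muscle`,
#'   `ongoing_emg`, `absolute_mep`, `mep_gain`, `included`.
#' @export
extract_stimulation_records <- function(emg, stim_index, rate, hs_right,
                                        coil = NULL) {
  muscles <- setdiff(names(emg), "time")
  n_stim <- length(stim_index)
  if (is.null(coil)) {
    coil <- data.frame(coil_vertical = numeric(n_stim),
                       coil_horizontal = numeric(n_stim))
  }
  stim_time <- (stim_index - 1L) / rate
  pct <- assign_cycle_percentage(stim_time, hs_right)
  out <- list()
  for (m in muscles) {
    filt <- bandpass_filter(emg[[m]], rate)
    ongoing <- vapply(stim_index, compute_ongoing_emg, numeric(1),
                      filtered = filt, rate = rate)
    mep <- vapply(stim_index, compute_absolute_mep, numeric(1),
                  filtered = filt, rate = rate)
    out[[m]] <- data.frame(
      stim = seq_len(n_stim), stim_time = stim_time, cycle_pct = pct,
      coil_vertical = coil$coil_vertical,
      coil_horizontal = coil$coil_horizontal,
      muscle = m, ongoing_emg = ongoing, absolute_mep = mep,
      mep_gain = compute_mep_gain(mep, ongoing))
  }
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  rec$included <- !is.na(rec$cycle_pct)
  class(rec) <- c("stimulation_records", "data.frame")
  rec
}

#' Apply coil-displacement and minimum-count exclusion rules
#'
#' A stimulation is excluded iff its coil displacement is strictly greater
#' than 5 mm vertically or strictly greater than 10 mm in the horizontal
#' plane. A participant-condition is flagged for exclusion when fewer than
#' `min_per_condition` stimulations survive.
#'
#' @param records a `stimulation_records` data frame.
#' @param vertical_mm,horizontal_mm exclusion thresholds (mm).
#' @param min_per_condition minimum surviving stimulations required.
#' @return list: `records` (with updated `included` flags),
#'   `n_surviving` (unique surviving stimulations) and
#'   `participant_included` (logical).
#' @export
apply_exclusions <- function(records, vertical_mm = 5, horizontal_mm = 10,
                             min_per_condition = 100L) {
  ok <- !(records$coil_vertical > vertical_mm |
            records$coil_horizontal > horizontal_mm)
  records$included <- records$included & ok
  surviving <- unique(records$stim[records$included])
  list(records = records,
       n_surviving = length(surviving),
       participant_included = length(surviving) >= min_per_condition)
}
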