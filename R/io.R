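# File interchange: plain CSV for time series (markers written in metres,
# EMG in microvolts), JSON for events, records and cluster results.

#' Write / read marker trajectories as CSV
#'
#' Markers are stored in metres on disk (the motion-capture convention) and
#' converted to millimetres in memory.
#'
#' @param series a `marker_series` (mm).
#' @param path CSV path.
#' @return `write_marker_csv` the path, invisibly; `read_marker_csv` a
#'   `marker_series` in mm.
#' @export
write_marker_csv <- function(series, path) {
  d <- series$data
  for (col in setdiff(names(d), "time")) d[[col]] <- d[[col]] / 1000
  utils::write.csv(cbind(d, rate = series$rate)[, c("time", "rate",
                                                    setdiff(names(d), "time"))],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_csv
#' @export
read_marker_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  rate <- d$rate[1]
  d$rate <- NULL
  for (col in setdiff(names(d), "time")) d[[col]] <- d[[col]] * 1000
  new_marker_series(d, rate)
}

#' Write / read EMG channels as CSV
#'
#' @param emg data frame: `time` plus one column per muscle (uV).
#' @param path CSV path.
#' @return the path invisibly / the data frame.
#' @export
write_emg_csv <- function(emg, path) {
  utils::write.csv(emg, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emg_csv
#' @export
read_emg_csv <- function(path) utils::read.csv(path, check.names = FALSE)

#' Write / read gait events as JSON
#'
#' @param events a [gait_events()] object.
#' @param path JSON path.
#' @return the path invisibly / a `gait_events`.
#' @export
write_events_json <- function(events, path) {
  jsonlite::write_json(unclass(events), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_events_json
#' @export
read_events_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gait_events(x$hs_left, x$hs_right, x$to_left, x$to_right)
}

#' Write stimulation records as CSV
#'
#' One row per stimulation x muscle.
#'
#' @param records a `stimulation_records` data frame.
#' @param path CSV path.
#' @return the path invisibly / the records.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  rec <- utils::read.csv(path, check.names = FALSE)
  class(rec) <- c("stimulation_records", "data.frame")
  rec
}

#' Write cluster-test results as JSON
#'
#' Cluster indices, spans in % of the gait cycle, masses and permutation
#' p-values, plus the null distribution summary.
#'
#' @param result a `cluster_permutation_result`.
#' @param path JSON path.
#' @param grid the [cyclic_grid()] the test was run on.
#' @return the path, invisibly.
#' @export
write_clusters_json <- function(result, path, grid = cyclic_grid()) {
  cl <- result$clusters
  out <- list(
    mode = result$mode,
    alpha = result$alpha,
    n_permutations = result$n_permutations,
    t_critical = result$t_critical,
    seed = result$seed,
    clusters = if (nrow(cl)) {
      cbind(cl, start_pct = grid$pct[cl$start_idx],
            end_pct = grid$pct[cl$end_idx])
    } else cl,
    null_max_mass_quantiles = as.list(quantile(result$null_max_mass,
                                               c(0.5, 0.9, 0.95, 0.99)))
  )
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}
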