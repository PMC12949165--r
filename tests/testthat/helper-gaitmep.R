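# Shared fixtures and independent oracles for the test suite.

# distance (s) from each true event to its nearest detected event
nearest_err <- function(detected, truth) {
  vapply(truth, function(x) min(abs(detected - x)), numeric(1))
}

# small noise-free session configuration used across tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(trial_duration = 60, marker_noise_sd = 0,
         muscles = c("tibialis_anterior", "rectus_femoris")),
    list(...))
  do.call(session_config, args)
}

# brute-force circular cluster enumeration: rotate so a run boundary is at
# position 1, then take linear runs; independent of the implementation
brute_clusters_cyclic <- function(tvals, t_crit) {
  n <- length(tvals)
  lab <- ifelse(abs(tvals) > t_crit, sign(tvals), 0)
  if (all(lab != 0) && length(unique(lab)) == 1L) {
    return(list(seq_len(n)))
  }
  z <- which(lab == 0 | c(lab[n], lab[-n]) != lab)[1]
  rot <- as.integer(((z - 1):(z + n - 2)) %% n + 1)
  lr <- lab[rot]
  runs <- rle(lr)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (k in which(runs$values != 0)) {
    out[[length(out) + 1L]] <- sort(rot[starts[k]:ends[k]])
  }
  out
}

# member indices of a cluster row returned by find_clusters_cyclic
cluster_members <- function(cl_row, n) {
  s <- cl_row$start_idx
  e <- cl_row$end_idx
  sort(as.integer(if (s <= e) s:e else c(s:n, 1:e)))
}

# deterministic logistic-map trajectory
logistic_series <- function(n, x0 = 0.34567) {
  x <- numeric(n)
  x[1] <- x0
  for (i in 2:n) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  x
}

# periodic thorax-like velocity signal with events for stability tests
limit_cycle_fixture <- function(duration = 60, rate = 100, period = 1.1) {
  t <- seq(0, duration, by = 1 / rate)
  v <- sin(2 * pi * t / period) + 0.5 * sin(4 * pi * t / period)
  hs <- seq(0.3, duration - period, by = period)
  ev <- gait_events(hs_left = hs + period / 2, hs_right = hs,
                    to_left = hs + 0.9 * period, to_right = hs + 0.4 * period)
  list(t = t, v = v, events = ev, rate = rate)
}
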