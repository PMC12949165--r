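#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx median quantile rnorm runif sd var qt rbinom acf
#' @importFrom rlang .data hash
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never clobbers it.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic child seed from a root seed and a named stream, so each
# participant/channel draws from an independent reproducible stream.
child_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(paste0(stream))) h <- (h * 31 + ch) %% 2147480009
  as.integer((as.numeric(seed) * 7919 + h) %% 2147480009)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid("`%s` must be a single positive finite number", name)
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop_invalid("`%s` must be a single non-negative finite number", name)
  }
  invisible(x)
}

# Central-difference derivative with one-sided differences at the ends.
central_diff <- function(x, rate) {
  n <- length(x)
  if (n < 3L) stop_invalid("series too short to differentiate")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2
  d[1] <- (x[2] - x[1]) * rate
  d[n] <- (x[n] - x[n - 1]) * rate
  d
}

# Zero-phase Butterworth low-pass (order 2 per pass).
lowpass_zero_phase <- function(x, rate, cutoff_hz, order = 2L) {
  if (cutoff_hz >= rate / 2) return(x)
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}
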