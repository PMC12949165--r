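#' Cyclic gait-phase grid
#'
#' Regular grid over the gait cycle: percentages `0, res, ..., 100 - res`,
#' covering `[0, 100)` exactly once.
#'
#' @param resolution grid spacing in % of the gait cycle; must divide 100.
#' @return object of class `cyclic_grid` with `pct` and `theta` (radians).
#' @export
cyclic_grid <- function(resolution = 0.5) {
  check_positive(resolution, "resolution")
  if (abs(100 / resolution - round(100 / resolution)) > 1e-9) {
    stop_invalid("resolution must divide 100")
  }
  pct <- seq(0, 100 - resolution, by = resolution)
  structure(list(pct = pct, theta = 2 * pi * pct / 100,
                 resolution = resolution), class = "cyclic_grid")
}

#' @export
print.cyclic_grid <- function(x, ...) {
  cat(sprintf("<cyclic_grid> %d points, %.2f%% resolution\n",
              length(x$pct), x$resolution))
  invisible(x)
}

#' Von Mises concentration equivalent to a Gaussian kernel width
#'
#' Converts a Gaussian kernel standard deviation expressed in % of the gait
#' cycle to the von Mises concentration with matching width, via the
#' large-kappa equivalence `kappa = 1 / sigma_rad^2` with
#' `sigma_rad = 2 * pi * sigma_pct / 100`. With `round_to_ten = TRUE` the
#' result is rounded to the nearest multiple of ten (so the conventional
#' sigma of 2% of the cycle gives kappa = 60).
#'
#' @param sigma_pct Gaussian SD in % of the gait cycle.
#' @param round_to_ten round the concentration to the nearest multiple of 10.
#' @return concentration `kappa`.
#' @export
kappa_from_sigma <- function(sigma_pct, round_to_ten = FALSE) {
  check_positive(sigma_pct, "sigma_pct")
  kappa <- 1 / (2 * pi * sigma_pct / 100)^2
  if (round_to_ten) kappa <- round(kappa / 10) * 10
  kappa
}

#' Von Mises kernel weight matrix
#'
#' `w[t, i] = exp(kappa * cos(theta_t - theta_i)) / (2 * pi * I0(kappa))`,
#' the von Mises density of sample `i` evaluated at grid point `t`;
#' periodic in both arguments. Computed via the exponentially scaled Bessel
#' function so large concentrations do not overflow.
#'
#' @param sample_pcts sample positions in % of the gait cycle.
#' @param grid a [cyclic_grid()].
#' @param kappa concentration.
#' @return matrix (grid points x samples).
#' @export
vonmises_weights <- function(sample_pcts, grid, kappa) {
  check_positive(kappa, "kappa")
  th_i <- 2 * pi * sample_pcts / 100
  dth <- outer(grid$theta, th_i, "-")
  # exp(k cos d) / (2 pi I0(k)) = exp(k (cos d - 1)) / (2 pi I0(k) e^-k)
  log_norm <- log(2 * pi) + log(besselI(kappa, 0, expon.scaled = TRUE))
  exp(kappa * (cos(dth) - 1) - log_norm)
}

#' Smooth sparse cyclic samples onto the grid
#'
#' Nadaraya-Watson regression with the von Mises kernel:
#' `values(t) = sum_i w(t,i) y_i / sum_i w(t,i)`; the denominator (the
#' kernel density) is kept as the per-point weight used for density
#' validity checks and weight-based group averaging. Samples with missing
#' values are dropped.
#'
#' @param sample_pcts sample positions (% of cycle).
#' @param values outcome at each sample.
#' @param grid a [cyclic_grid()].
#' @param kappa concentration; default the sigma = 2% equivalent rounded to
#'   ten (60).
#' @param sigma_pct Gaussian-equivalent width used for the density rule.
#' @param min_count minimum samples within 2 sigma for a grid point to be
#'   valid.
#' @return object of class `smoothed_cyclic`: `pct`, `values`, `density`,
#'   `valid`, `kappa`, `sigma_pct`, `n_samples`.
#' @export
smooth_cyclic <- function(sample_pcts, values, grid = cyclic_grid(),
                          kappa = kappa_from_sigma(2, round_to_ten = TRUE),
                          sigma_pct = 2, min_count = 6L) {
  keep <- !is.na(sample_pcts) & !is.na(values)
  sample_pcts <- sample_pcts[keep]
  values <- values[keep]
  if (!length(values)) stop_invalid("no usable samples to smooth")
  W <- vonmises_weights(sample_pcts, grid, kappa)
  dens <- rowSums(W)
  vals <- as.numeric(W %*% values) / dens
  valid <- check_density_rule(sample_pcts, grid, sigma_pct, min_count)
  structure(list(pct = grid$pct, values = vals, density = dens,
                 valid = valid, kappa = kappa, sigma_pct = sigma_pct,
                 n_samples = length(values)), class = "smoothed_cyclic")
}

#' @export
print.smoothed_cyclic <- function(x, ...) {
  cat(sprintf("<smoothed_cyclic> %d grid points from %d samples (kappa %g), %d%% valid\n",
              length(x$pct), x$n_samples, x$kappa,
              round(100 * mean(x$valid))))
  invisible(x)
}

#' Kernel density validity flags
#'
#' A grid point is valid when at least `min_count` samples lie within a
#' circular distance of two kernel standard deviations of it.
#'
#' @inheritParams smooth_cyclic
#' @return logical vector over the grid.
#' @export
check_density_rule <- function(sample_pcts, grid, sigma_pct = 2,
                               min_count = 6L) {
  sample_pcts <- sample_pcts[!is.na(sample_pcts)]
  d <- abs(outer(grid$pct, sample_pcts, "-")) %% 100
  d <- pmin(d, 100 - d)
  rowSums(d <= 2 * sigma_pct + 1e-9) >= min_count
}

#' Group-average smoothed curves across participants
#'
#' Unweighted: the plain mean across participants at every grid point.
#' Weighted: each participant's contribution is proportional to their local
#' kernel density, `w_hat_p(t) = density_p(t) / sum_q density_q(t)`, so
#' participants with more stimulations near a phase point dominate there.
#'
#' @param series list of `smoothed_cyclic` objects on a common grid.
#' @param mode `"weighted"` or `"unweighted"`.
#' @return list: `pct`, `values` (group curve), `weights` (participants x
#'   grid, normalised; equal weights in unweighted mode), `sd` (across
#'   participants).
#' @export
group_average <- function(series, mode = c("unweighted", "weighted")) {
  mode <- match.arg(mode)
  if (length(series) < 2L) stop_invalid("need at least two participants")
  pct <- series[[1]]$pct
  for (s in series) {
    if (length(s$pct) != length(pct) || any(s$pct != pct)) {
      stop_invalid("smoothed series are on different grids")
    }
  }
  V <- do.call(rbind, lapply(series, `[[`, "values"))
  D <- do.call(rbind, lapply(series, `[[`, "density"))
  if (mode == "weighted") {
    Wh <- sweep(D, 2, colSums(D), "/")
  } else {
    Wh <- matrix(1 / nrow(V), nrow(V), ncol(V))
  }
  list(pct = pct, values = colSums(Wh * V), weights = Wh,
       sd = apply(V, 2, sd), mode = mode)
}
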