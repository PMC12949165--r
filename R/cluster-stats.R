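T_CAP <- 1e6  # replaces infinite t at zero variance, with a flag

#' Pointwise paired t-statistics on cyclic curves
#'
#' Unweighted mode is the classical paired t-test at every grid point.
#' Weighted mode tests the weighted mean condition difference
#' `dbar_w(t) = sum_p w_hat_p(t) d_p(t)` with reliability-weighted variance
#' `s2_w(t) = sum_p w_hat_p (d_p - dbar_w)^2 / (1 - sum_p w_hat_p^2)` and
#' standard error `sqrt(s2_w * sum_p w_hat_p^2)`; with equal weights this
#' reduces exactly to the classical paired t. Zero-variance points with a
#' non-zero mean difference are capped at a large finite t and flagged.
#'
#' @param curves_a,curves_b matrices (participants x grid points) of the
#'   two conditions, participants in the same order.
#' @param mode `"unweighted"` or `"weighted"`.
#' @param weights normalised participant weights (participants x grid,
#'   columns summing to one); required for weighted mode.
#' @return list: `t` (per grid point), `df`, `capped` (logical flags).
#' @export
pointwise_paired_t <- function(curves_a, curves_b,
                               mode = c("unweighted", "weighted"),
                               weights = NULL) {
  mode <- match.arg(mode)
  if (!all(dim(curves_a) == dim(curves_b))) {
    stop_invalid("condition matrices must have identical dimensions")
  }
  n <- nrow(curves_a)
  if (n < 2L) stop_invalid("need at least two participants")
  d <- curves_a - curves_b
  if (mode == "unweighted") {
    mean_d <- colMeans(d)
    se <- apply(d, 2, sd) / sqrt(n)
  } else {
    if (is.null(weights) || !all(dim(weights) == dim(d))) {
      stop_invalid("weighted mode needs a participants x grid weight matrix")
    }
    csum <- colSums(weights)
    if (any(abs(csum - 1) > 1e-8)) {
      stop_invalid("weight columns must sum to one")
    }
    mean_d <- colSums(weights * d)
    wsq <- colSums(weights^2)
    s2 <- colSums(weights * sweep(d, 2, mean_d)^2) / (1 - wsq)
    se <- sqrt(s2 * wsq)
  }
  tval <- mean_d / se
  tval[se == 0 & mean_d == 0] <- 0
  tval[se == 0 & mean_d != 0] <- sign(mean_d[se == 0 & mean_d != 0]) * T_CAP
  tval[is.na(tval)] <- 0
  capped <- abs(tval) >= T_CAP
  tval <- pmin(pmax(tval, -T_CAP), T_CAP)
  list(t = tval, df = n - 1L, capped = capped)
}

#' Find clusters of consecutively significant points on a cyclic grid
#'
#' Maximal runs of consecutive grid points with `|t| > t_critical` and a
#' constant sign. A run touching the first and a run touching the last
#' index with the same sign are merged into one wrapped cluster, honouring
#' the cyclic nature of the gait cycle. Cluster mass is the sum of the
#' member t-values.
#'
#' @param tvals t-statistics over the full cyclic grid.
#' @param t_critical positive significance threshold (strict inequality).
#' @return data frame with one row per cluster: `start_idx`, `end_idx`
#'   (1-based, wrap-around when `end_idx < start_idx`), `size`, `sign`,
#'   `mass`.
#' @export
find_clusters_cyclic <- function(tvals, t_critical) {
  n <- length(tvals)
  sig <- abs(tvals) > t_critical & is.finite(tvals)
  sgn <- sign(tvals)
  lab <- ifelse(sig, sgn, 0)
  if (!any(sig)) {
    return(data.frame(start_idx = integer(0), end_idx = integer(0),
                      size = integer(0), sign = integer(0),
                      mass = numeric(0)))
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  cl <- data.frame(start_idx = starts[keep], end_idx = ends[keep],
                   sign = r$values[keep])
  # wrap-around merge: first and last runs both significant with same sign
  if (nrow(cl) > 1L && cl$start_idx[1] == 1L &&
      cl$end_idx[nrow(cl)] == n &&
      cl$sign[1] == cl$sign[nrow(cl)]) {
    cl$start_idx[1] <- cl$start_idx[nrow(cl)]
    cl <- cl[-nrow(cl), , drop = FALSE]
  }
  idx_of <- function(s, e) if (s <= e) s:e else c(s:n, 1:e)
  cl$size <- mapply(function(s, e) length(idx_of(s, e)),
                    cl$start_idx, cl$end_idx)
  cl$mass <- mapply(function(s, e) sum(tvals[idx_of(s, e)]),
                    cl$start_idx, cl$end_idx)
  cl[, c("start_idx", "end_idx", "size", "sign", "mass")]
}

#' Cyclic cluster-based permutation test for paired condition curves
#'
#' Observed clusters are formed from pointwise paired t-statistics
#' thresholded at the two-sided Student critical value. The null
#' distribution is built by randomly exchanging the two condition labels
#' within each participant (equivalently sign-flipping the paired
#' difference curves; kernel smoothing is linear and per
#' participant-condition, so permuting stimulation-level data and
#' re-smoothing yields exactly these flipped curves) and recording the
#' maximum absolute cluster mass of each permutation (0 when a permutation
#' yields no cluster). A cluster's p-value is the fraction of null values
#' at or above its absolute mass, floored at `1/n_permutations`; it is
#' significant when its absolute mass exceeds the 95th percentile of the
#' null distribution.
#'
#' @inheritParams pointwise_paired_t
#' @param n_permutations number of permutations (protocol default: 1000).
#' @param alpha pointwise and cluster significance level.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return object of class `cluster_permutation_result`: `clusters` (with
#'   `p_value` and `significant`), `null_max_mass`, `t`, `t_critical`,
#'   `alpha`, `n_permutations`, `seed`, `mode`.
#' @export
cluster_permutation_test <- function(curves_a, curves_b,
                                     mode = c("unweighted", "weighted"),
                                     weights = NULL, n_permutations = 1000L,
                                     alpha = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  if (n_permutations < 100L) {
    warning("fewer than 100 permutations gives a coarse null", call. = FALSE)
  }
  n <- nrow(curves_a)
  pt <- pointwise_paired_t(curves_a, curves_b, mode, weights)
  t_crit <- qt(1 - alpha / 2, df = pt$df)
  obs <- find_clusters_cyclic(pt$t, t_crit)
  d <- curves_a - curves_b
  null_max <- numeric(n_permutations)
  perm_t <- function(dp) {
    if (mode == "unweighted") {
      mean_d <- colMeans(dp)
      se <- sqrt(colSums(sweep(dp, 2, mean_d)^2) / (n - 1L)) / sqrt(n)
    } else {
      mean_d <- colSums(weights * dp)
      wsq <- colSums(weights^2)
      se <- sqrt(colSums(weights * sweep(dp, 2, mean_d)^2) / (1 - wsq) * wsq)
    }
    tv <- mean_d / se
    tv[se == 0 & mean_d == 0] <- 0
    tv[se == 0 & mean_d != 0] <- sign(mean_d[se == 0 & mean_d != 0]) * T_CAP
    tv[is.na(tv)] <- 0
    pmin(pmax(tv, -T_CAP), T_CAP)
  }
  with_seed(seed, {
    for (r in seq_len(n_permutations)) {
      flips <- sample(c(-1, 1), n, replace = TRUE)
      cl <- find_clusters_cyclic(perm_t(flips * d), t_crit)
      null_max[r] <- if (nrow(cl)) max(abs(cl$mass)) else 0
    }
  })
  if (nrow(obs)) {
    obs$p_value <- pmax(vapply(abs(obs$mass),
                               function(m) mean(null_max >= m), numeric(1)),
                        1 / n_permutations)
    crit95 <- quantile(null_max, 1 - alpha, names = FALSE, type = 1)
    obs$significant <- abs(obs$mass) > crit95
  } else {
    obs$p_value <- numeric(0)
    obs$significant <- logical(0)
  }
  structure(list(clusters = obs, null_max_mass = null_max, t = pt$t,
                 t_critical = t_crit, alpha = alpha,
                 n_permutations = n_permutations, seed = seed, mode = mode),
            class = "cluster_permutation_result")
}

#' @export
print.cluster_permutation_result <- function(x, ...) {
  cat(sprintf("<cluster_permutation_result> %s, %d permutations, t_crit %.2f\n",
              x$mode, x$n_permutations, x$t_critical))
  if (nrow(x$clusters)) {
    for (i in seq_len(nrow(x$clusters))) {
      cl <- x$clusters[i, ]
      cat(sprintf("  cluster %d: idx %d..%d (n=%d), mass %.1f, p=%.3f%s\n",
                  i, cl$start_idx, cl$end_idx, cl$size, cl$mass, cl$p_value,
                  if (cl$significant) " *" else ""))
    }
  } else {
    cat("  no clusters\n")
  }
  invisible(x)
}

#' Cluster-based permutation test from stimulation-level records
#'
#' Smooths each participant-condition's sparse stimulation samples onto the
#' cyclic grid (von Mises kernel) and runs [cluster_permutation_test()].
#' Because the smoother is linear and operates per participant-condition,
#' exchanging condition labels at the stimulation level and re-smoothing is
#' identical to exchanging the pre-smoothed curves, which is how the
#' permutations are evaluated. In weighted mode the participant weights are
#' taken from the combined-condition kernel densities (invariant under
#' label exchange).
#'
#' @param samples_a,samples_b per-participant lists of data frames with
#'   columns `cycle_pct` and `value` for the two conditions.
#' @param grid a [cyclic_grid()].
#' @param kappa,sigma_pct kernel parameters (see [smooth_cyclic()]).
#' @inheritParams cluster_permutation_test
#' @return a `cluster_permutation_result`; participant curves are attached
#'   as `curves_a`/`curves_b`.
#' @export
cluster_permutation_test_records <- function(samples_a, samples_b,
                                             grid = cyclic_grid(),
                                             kappa = kappa_from_sigma(2, TRUE),
                                             sigma_pct = 2,
                                             mode = c("unweighted", "weighted"),
                                             n_permutations = 1000L,
                                             alpha = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  if (length(samples_a) != length(samples_b)) {
    stop_invalid("both conditions need the same participants")
  }
  sm <- function(df) smooth_cyclic(df$cycle_pct, df$value, grid, kappa,
                                   sigma_pct)
  sa <- lapply(samples_a, sm)
  sb <- lapply(samples_b, sm)
  A <- do.call(rbind, lapply(sa, `[[`, "values"))
  B <- do.call(rbind, lapply(sb, `[[`, "values"))
  weights <- NULL
  if (mode == "weighted") {
    Dcomb <- do.call(rbind, lapply(seq_along(sa), function(p) {
      sa[[p]]$density + sb[[p]]$density
    }))
    weights <- sweep(Dcomb, 2, colSums(Dcomb), "/")
  }
  res <- cluster_permutation_test(A, B, mode, weights, n_permutations,
                                  alpha, seed)
  res$curves_a <- A
  res$curves_b <- B
  res
}

#' Paired t-test for scalar gait outcomes
#'
#' Classical two-sided paired Student t-test, with an explicit degenerate
#' flag when the paired differences have zero variance.
#'
#' @param values_a,values_b paired per-participant values.
#' @return list: `t`, `df`, `p_value`, `mean_difference`, `degenerate`.
#' @export
paired_t_scalar <- function(values_a, values_b) {
  if (length(values_a) != length(values_b) || length(values_a) < 2L) {
    stop_invalid("need paired samples with n >= 2")
  }
  d <- values_a - values_b
  n <- length(d)
  if (sd(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * T_CAP,
                df = n - 1L,
                p_value = if (mean(d) == 0) 1 else 0,
                mean_difference = mean(d), degenerate = TRUE))
  }
  tval <- mean(d) / (sd(d) / sqrt(n))
  list(t = tval, df = n - 1L,
       p_value = 2 * stats::pt(-abs(tval), df = n - 1L),
       mean_difference = mean(d), degenerate = FALSE)
}
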