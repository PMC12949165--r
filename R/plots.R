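#' Plot group condition curves with significant clusters
#'
#' Mean curves per condition over the gait cycle with between-participant
#' SD ribbons; phases belonging to significant clusters are shaded grey.
#'
#' @param result a `cluster_permutation_result` carrying `curves_a`
#'   (destabilised) and `curves_b` (steady), as returned by
#'   [cluster_permutation_test_records()].
#' @param grid the [cyclic_grid()] used.
#' @param title plot title.
#' @param ylab y-axis label (outcome units).
#' @return a ggplot object.
#' @export
plot_condition_curves <- function(result, grid = cyclic_grid(),
                                  title = NULL, ylab = "outcome") {
  if (is.null(result$curves_a)) {
    stop_invalid("result carries no participant curves; run the records-level test")
  }
  pct <- grid$pct
  df <- rbind(
    data.frame(pct = pct, condition = "destabilised",
               mean = colMeans(result$curves_a),
               sd = apply(result$curves_a, 2, sd)),
    data.frame(pct = pct, condition = "steady",
               mean = colMeans(result$curves_b),
               sd = apply(result$curves_b, 2, sd))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pct, y = .data$mean,
                                        colour = .data$condition,
                                        fill = .data$condition))
  cl <- result$clusters
  if (nrow(cl)) {
    for (i in which(cl$significant)) {
      s <- pct[cl$start_idx[i]]
      e <- pct[cl$end_idx[i]]
      if (s <= e) {
        p <- p + ggplot2::annotate("rect", xmin = s, xmax = e,
                                   ymin = -Inf, ymax = Inf,
                                   alpha = 0.25, fill = "grey40")
      } else {  # wrapped cluster: two shaded blocks
        p <- p + ggplot2::annotate("rect", xmin = s, xmax = 100,
                                   ymin = -Inf, ymax = Inf,
                                   alpha = 0.25, fill = "grey40") +
          ggplot2::annotate("rect", xmin = 0, xmax = e,
                            ymin = -Inf, ymax = Inf,
                            alpha = 0.25, fill = "grey40")
      }
    }
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "gait cycle (%)", y = ylab, title = title) +
    ggplot2::theme_minimal()
}

#' Plot a mean log-divergence curve
#'
#' @param curve a `divergence_curve`.
#' @param fit_window slope window highlighted (strides).
#' @return a ggplot object.
#' @export
plot_divergence_curve <- function(curve, fit_window = c(0, 0.5)) {
  df <- data.frame(time = curve$time, logd = curve$log_divergence)
  lambda <- estimate_lambda_s(curve, fit_window)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$logd)) +
    ggplot2::annotate("rect", xmin = fit_window[1], xmax = fit_window[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.15,
                      fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (strides)", y = "mean log divergence",
                  subtitle = sprintf("lambda_s = %.3f / stride", lambda)) +
    ggplot2::theme_minimal()
}
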