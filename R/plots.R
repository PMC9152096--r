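#' Plot methods
#'
#' ggplot2 graphics for the pipeline's result objects: sweep curves
#' (accuracy against ensemble size or subspace dimensionality), benchmark
#' box plots across repeated splits, precision-recall curves per method,
#' and ROI weight bars.
#'
#' @param object A `sweep_result` or `benchmark_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  df <- object$results
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$mean_accuracy)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 1.6) +
    ggplot2::geom_vline(xintercept = object$selected, linetype = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = object$parameter, y = "mean test accuracy",
                  title = sprintf("Sweep of %s (selected %d, rule: %s)",
                                  object$parameter, object$selected, object$rule)) +
    ggplot2::theme_minimal()
  if (!all(is.na(df$sd_accuracy)))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$sd_accuracy,
                   ymax = .data$mean_accuracy + .data$sd_accuracy),
      alpha = 0.15)
  p
}

#' @rdname plots
#' @method autoplot benchmark_result
#' @export
autoplot.benchmark_result <- function(object, ...) {
  ggplot2::ggplot(object$accuracies,
                  ggplot2::aes(x = .data$method, y = .data$accuracy)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "test accuracy",
                  title = "Classification accuracy across repeated splits") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param benchmark A `benchmark_result` from [run_baselines()].
#' @export
plot_pr_curves <- function(benchmark, ...) {
  curves <- dplyr::bind_rows(lapply(unique(benchmark$scores$method), function(m) {
    s <- benchmark$scores[benchmark$scores$method == m, ]
    dplyr::mutate(pr_curve(s$score, s$label), method = m)
  }))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$recall, y = .data$precision,
                                       colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision",
                  title = "Precision-recall curves") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param weights An `roi_weight_table` from [roi_weights()].
#' @param top_k Number of ROIs shown.
#' @export
plot_roi_weights <- function(weights, top_k = 20L, ...) {
  df <- utils::head(weights, top_k)
  df$name <- factor(df$name, levels = rev(df$name))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, y = .data$name)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "weight (appearances in optimal edges)", y = NULL,
                  title = "Candidate pathogenic regions") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
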