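# ggplot2 views of the main result types. These return plot objects; data
# used for plotting is always available as plain tibbles too.

#' Plot composite window scores along a chromosome
#'
#' @param windows Output of [scan_windows()].
#' @param score_threshold Optional horizontal reference line at the
#'   locus-calling threshold.
#' @return A ggplot object.
#' @export
plot_window_scores <- function(windows, score_threshold = NULL) {
  check_columns(windows, c("start", "end", "score", "chrom"), "`windows`")
  p <- ggplot2::ggplot(windows, ggplot2::aes(
    x = (.data$start + .data$end) / 2e6, y = .data$score
  )) +
    ggplot2::geom_segment(ggplot2::aes(xend = (.data$start + .data$end) / 2e6,
                                       yend = 0), linewidth = 0.3) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "composite window score") +
    ggplot2::theme_minimal()
  if (!is.null(score_threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = score_threshold,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Plot relative expression by group
#'
#' @param values Output of [relative_expression()].
#' @param log_scale Show the fold axis on a log2 scale.
#' @return A ggplot object.
#' @export
plot_relative_expression <- function(values, log_scale = TRUE) {
  check_columns(values, c("group", "value"), "`values`")
  p <- ggplot2::ggplot(values, ggplot2::aes(.data$group, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "relative expression (fold)") +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_continuous(trans = "log2")
  p
}

#' @rdname roc_auc
#' @param object A `roc_result`.
#' @param ... Unused.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  pts <- tidy(object)
  ggplot2::ggplot(pts, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("AUC = %.3f (95%% CI %.2f-%.2f)",
                      object$auc, object$ci_low, object$ci_high)
    ) +
    ggplot2::theme_minimal()
}

#' Normal P-P plot
#'
#' @param values Numeric vector, or a precomputed [pp_points()] tibble.
#' @return A ggplot object.
#' @export
plot_pp <- function(values) {
  pts <- if (is.data.frame(values)) values else pp_points(values)
  check_columns(pts, c("theoretical", "empirical"), "`values`")
  ggplot2::ggplot(pts, ggplot2::aes(.data$theoretical, .data$empirical)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal(xlim = 0:1, ylim = 0:1) +
    ggplot2::labs(x = "theoretical cumulative probability",
                  y = "empirical cumulative probability") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
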