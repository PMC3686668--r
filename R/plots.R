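#' Plot a ROC curve
#'
#' ROC curve in (1 - SP, SE) space with points shaded by the geometric
#' mean, so the Gm-optimal region is visible at a glance.
#'
#' @param object A [roc_curve_points()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mirhunt_roc <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 100 - .data$sp, y = .data$se)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$gm), size = 1.6) +
    ggplot2::scale_colour_viridis_c(name = "Gm") +
    ggplot2::labs(x = "100 - specificity", y = "sensitivity",
                  title = "ROC curve over pooled out-of-fold scores") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot a fitted ROC-select model
#'
#' The pooled ROC curve with the selected operating point marked.
#'
#' @param object A [roc_select_fit()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_select_fit <- function(object, ...) {
  autoplot.mirhunt_roc(object$roc) +
    ggplot2::geom_point(
      data = tibble::as_tibble(object$selected),
      ggplot2::aes(x = 100 - .data$sp, y = .data$se),
      shape = 21, size = 4, stroke = 1.1, colour = "red", fill = NA) +
    ggplot2::labs(subtitle = sprintf("selected threshold %.4g (pooled Gm %.2f)",
                                     object$threshold, object$selected$gm))
}

#' Plot a grid-search profile
#'
#' Mean evaluation metric against the first grid axis (additional axes are
#' mapped to colour).
#'
#' @param object A [grid_search()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mirhunt_grid_search <- function(object, ...) {
  tab <- object$table
  axes <- setdiff(names(tab), c("mean_metric", "rank"))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data[[axes[1]]], y = .data$mean_metric))
  if (length(axes) > 1) {
    p <- p + ggplot2::aes(colour = factor(.data[[axes[2]]])) +
      ggplot2::labs(colour = axes[2])
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = "mean metric over folds",
                  title = "Parameter grid search") +
    ggplot2::theme_minimal()
}

#' Critical-difference diagram data plot
#'
#' Average ranks from a [friedman_nemenyi()] analysis on a number line with
#' the Nemenyi critical difference drawn as a reference bar; methods whose
#' ranks differ by less than CD are not significantly different.
#'
#' @param x A [friedman_nemenyi()] result.
#' @return A ggplot.
#' @export
plot_critical_difference <- function(x) {
  stopifnot(inherits(x, "mirhunt_friedman"))
  df <- tidy.mirhunt_friedman(x)
  df$y <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg_rank, y = .data$y)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$method), vjust = -1, size = 3.2) +
    ggplot2::annotate("segment", x = min(df$avg_rank),
                      xend = min(df$avg_rank) + x$cd,
                      y = 0.4, yend = 0.4, linewidth = 1.2) +
    ggplot2::annotate("text", x = min(df$avg_rank) + x$cd / 2, y = 0.25,
                      label = sprintf("CD = %.2f", x$cd), size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, nrow(df) + 1), breaks = NULL) +
    ggplot2::labs(x = "average rank (1 = best)", y = NULL,
                  title = "Critical-difference diagram") +
    ggplot2::theme_minimal()
}
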