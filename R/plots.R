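#' Plot a domain pair in its first two feature dimensions
#'
#' @param object A `domain_pair`.
#' @param ... Unused.
#' @return A ggplot: source vs target panels, points colored by class.
#' @method autoplot domain_pair
#' @export
autoplot.domain_pair <- function(object, ...) {
  df <- as_tibble.domain_pair(object)
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$x1, y = .data$x2, colour = factor(.data$label),
                 shape = .data$role)
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~domain) +
    ggplot2::labs(colour = "class", shape = "role",
                  title = "Source and target feature distributions") +
    ggplot2::theme_minimal()
}

#' Plot post-hoc benchmark comparisons
#'
#' Bars show the z statistic of each method against the best-ranked method;
#' fill marks the Holm step-down decision.
#'
#' @param object A [benchmark_stats()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot benchmark_stats
#' @export
autoplot.benchmark_stats <- function(object, ...) {
  df <- object$posthoc
  df$method <- factor(df$method, levels = rev(df$method))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$method,
                                   fill = .data$reject)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "z vs best-ranked method", y = NULL, fill = "Holm reject",
      title = sprintf("Post-hoc comparisons against %s", object$best_method),
      subtitle = sprintf("Friedman Q = %.4g, p = %.4g",
                         object$friedman$q_stat, object$friedman$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a parameter sweep
#'
#' @param object An `elsr_sweep` tibble from [sweep_parameter()].
#' @param ... Unused.
#' @return A ggplot of accuracy against the swept parameter (log x-axis when
#'   the grid spans orders of magnitude).
#' @method autoplot elsr_sweep
#' @export
autoplot.elsr_sweep <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = object$parameter[1L], y = "test accuracy",
                  title = sprintf("Sensitivity to %s", object$parameter[1L])) +
    ggplot2::theme_minimal()
  vals <- object$value
  if (min(vals) > 0 && max(vals) / min(vals) > 100) {
    p <- p + ggplot2::scale_x_log10()
  }
  p
}

#' @importFrom rlang .data
NULL
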