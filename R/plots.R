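#' Plot population trajectories in PC space
#'
#' @param object A `trajectory_result`.
#' @param ... Unused.
#' @return A ggplot: PC1 vs PC2 paths per condition, stimulus onset marked.
#' @method autoplot trajectory_result
#' @export
autoplot.trajectory_result <- function(object, ...) {
  s <- object$scores
  onset <- dplyr::slice_min(dplyr::group_by(
    dplyr::filter(s, .data$time_s >= 0), .data$condition),
    .data$time_s, n = 1, with_ties = FALSE)
  ggplot2::ggplot(s, ggplot2::aes(.data$PC1, .data$PC2,
                                  colour = .data$condition)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = onset, shape = 16, size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * object$explained_variance[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * object$explained_variance[2]),
      colour = NULL,
      title = "Population activity trajectories") +
    ggplot2::theme_minimal()
}

#' Plot a decoding accuracy distribution
#'
#' @param object A `decode_result`.
#' @param ... Unused.
#' @return A ggplot histogram of per-repeat accuracies with chance level.
#' @method autoplot decode_result
#' @export
autoplot.decode_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "zero-one accuracy", y = "repeats",
                  title = sprintf("%s → %s (%s)", object$train_scope,
                                  object$test_scope, object$scheme)) +
    ggplot2::theme_minimal()
}

#' Plot the learning-rate trajectory of a SARSA simulation ensemble
#'
#' @param object A `sarsa_sim`.
#' @param ... Unused.
#' @return A ggplot of mean learning rate (with s.e.m. band) over
#'   modelled trials.
#' @method autoplot sarsa_sim
#' @export
autoplot.sarsa_sim <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(mean_alpha = mean(.data$alpha),
                     sem = sd(.data$alpha) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$trial, .data$mean_alpha)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_alpha - .data$sem,
                                      ymax = .data$mean_alpha + .data$sem),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "modelled trial", y = "learning rate α",
                  title = paste("Adaptive learning rate:", object$session)) +
    ggplot2::theme_minimal()
}

#' Plot per-phase mean learning rates
#'
#' @param summary Output of [learning_rate_summary()].
#' @return A ggplot of mean alpha per session phase with CI bars.
#' @export
plot_learning_rates <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(.data$phase, .data$mean_alpha,
                               colour = .data$session,
                               group = .data$session)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.1) +
    ggplot2::labs(x = NULL, y = "mean learning rate α", colour = NULL) +
    ggplot2::theme_minimal()
}
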