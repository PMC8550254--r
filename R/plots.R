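# Diagnostic figures: schedule trajectories, posterior marginals, fitted
# learning rates and win-driven proportions.

#' Plot a session's outcome-probability schedule
#'
#' Step traces of the win and loss outcome-on-A probabilities across the
#' five blocks, the standard way these designs are displayed.
#'
#' @param session A session schedule tibble from [build_session()] (or a
#'   single participant-session slice of a trial log).
#' @return A ggplot object.
#' @export
#' @examples
#' plot_schedule(build_session("negative_training", seed = 3))
plot_schedule <- function(session) {
  long <- session |>
    dplyr::mutate(global_trial = (block_index - 1L) * max(trial) + trial) |>
    tidyr::pivot_longer(c(p_win_A, p_loss_A), names_to = "valence",
                        names_pattern = "p_(.*)_A", values_to = "probability")
  ggplot2::ggplot(long, ggplot2::aes(.data$global_trial, probability,
                                     colour = valence)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::geom_vline(
      xintercept = max(session$trial) * seq_len(max(session$block_index) - 1) + 0.5,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::scale_colour_manual(values = c(win = "#2e7d32", loss = "#c62828")) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "trial", y = "P(outcome over stimulus A)",
                  colour = "outcome") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.iblt_fit <- function(object, ...) {
  ggplot2::ggplot(object$marginals, ggplot2::aes(value, mass)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "parameter value", y = "marginal posterior mass") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot fitted learning rates by block and valence
#'
#' @param param_table Output of [fit_dataset()].
#' @return A ggplot object.
#' @export
plot_learning_rates <- function(param_table) {
  long <- param_table |>
    tidyr::pivot_longer(c(alpha_win, alpha_loss), names_to = "valence",
                        names_prefix = "alpha_", values_to = "alpha")
  ggplot2::ggplot(long, ggplot2::aes(factor(block_index), .data$alpha,
                                     fill = valence)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::scale_fill_manual(values = c(win = "#66bb6a", loss = "#ef5350")) +
    ggplot2::labs(x = "block", y = "fitted learning rate",
                  fill = "outcome") +
    ggplot2::theme_minimal()
}

#' Plot win-driven choice proportions by block
#'
#' @param choice_table Output of [win_driven_table()].
#' @return A ggplot object.
#' @export
plot_win_driven <- function(choice_table) {
  ggplot2::ggplot(choice_table,
                  ggplot2::aes(factor(block_index), p_win_driven)) +
    ggplot2::geom_boxplot(fill = "#90caf9", outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "block", y = "proportion win-driven choices") +
    ggplot2::theme_minimal()
}
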