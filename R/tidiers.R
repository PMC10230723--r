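# broom-style accessors and ggplot2 autoplot methods for the result types.

#' Tidy a fitted binding-site classifier
#'
#' @param x An `rbp_fit`.
#' @param ... Unused.
#' @return The per-epoch training history: `epoch`, `lr`, `loss`, `acc`,
#'   `auc`.
#' @export
tidy.rbp_fit <- function(x, ...) x$history

#' One-row summary of a fitted binding-site classifier
#'
#' @param x An `rbp_fit`.
#' @param ... Unused.
#' @return One-row tibble with the held-out metrics plus `n_train`,
#'   `n_test`, `seed` and `split_hash`.
#' @export
glance.rbp_fit <- function(x, ...) {
  mutate(x$metrics[, c("acc", "auc", "precision", "recall")],
         n_train = x$n_train, n_test = x$n_test,
         seed = x$seed, split_hash = x$split_hash)
}

#' Plot the training history of a fit
#'
#' @param object An `rbp_fit`.
#' @param ... Unused.
#' @return A ggplot: loss, train ACC and train AUC against epoch.
#' @export
autoplot.rbp_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("loss", "acc", "auc"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}

#' Plot a gradient depth profile
#'
#' @param object An `rbp_grad_profile` from [gradient_depth_profile()].
#' @param ... Unused.
#' @return A ggplot of the per-block input-gradient norms against depth.
#' @export
autoplot.rbp_grad_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$depth, y = .data$grad_norm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "block (input)", y = "|| dLoss / d input ||",
                  title = sprintf("Gradient propagation depth profile (%s-norm)",
                                  object$norm_style[1L])) +
    ggplot2::theme_minimal()
}

#' Plot an ablation table
#'
#' @param object An `rbp_ablation` from [ablate()].
#' @param ... Unused.
#' @return A ggplot bar chart of AUC per configuration.
#' @export
autoplot.rbp_ablation <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$config, y = .data$auc)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::coord_cartesian(ylim = c(0.5, 1)) +
    ggplot2::labs(x = NULL, y = "held-out AUC",
                  title = sprintf("Ablation: %s", attr(object, "axis"))) +
    ggplot2::theme_minimal()
}

#' Plot a stability study
#'
#' @param object An `rbp_stability` from [stability_run()].
#' @param ... Unused.
#' @return A ggplot of per-run AUC, one line per wiring style.
#' @export
autoplot.rbp_stability <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$run, y = .data$auc,
                               colour = .data$norm_style)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "run", y = "held-out AUC", colour = "wiring",
                  title = "Run-to-run stability") +
    ggplot2::theme_minimal()
}
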