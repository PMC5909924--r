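#' Plot a training loss trace
#'
#' Regularized cost per full-batch iteration; with dropout active the
#' trace is the masked-network cost, so some iteration-to-iteration noise
#' is expected.
#'
#' @param object An [nncox()] fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nncox_fit <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$loss_trace), cost = object$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$cost)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(
      x = "Iteration", y = "Regularized cost (-partial log-likelihood + penalty)",
      title = sprintf("Training trace (%s, lr decay %.2g)",
                      object$config$optimizer, object$config$lr_decay)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation profile
#'
#' Mean validation concordance per hyperparameter setting, with per-fold
#' points; the selected setting is highlighted.
#'
#' @param object An `nncox_cv` from [cv_search()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nncox_cv <- function(object, ...) {
  long <- tidy(object)
  prof <- object$profile |>
    dplyr::mutate(setting = paste0("ridge=", .data$ridge, "\np=", .data$dropout))
  long <- long |>
    dplyr::mutate(setting = paste0("ridge=", .data$ridge, "\np=", .data$dropout))
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$setting, y = .data$mean_score)) +
    ggplot2::geom_point(data = long, ggplot2::aes(y = .data$score),
                        color = "grey60", alpha = 0.7, size = 1) +
    ggplot2::geom_point(ggplot2::aes(color = .data$selected), size = 3) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                guide = "none") +
    ggplot2::labs(x = "Hyperparameter setting", y = "Validation C-index",
                  title = "Cross-validation profile") +
    ggplot2::theme_minimal()
}

#' Plot hidden-node contribution profiles
#'
#' Heat-map style tile plot of node contributions across patients for the
#' top-variance nodes, ordered by variance.
#'
#' @param object An `nncox_contributions` matrix from
#'   [node_contributions()].
#' @param k Number of top-variance nodes to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nncox_contributions <- function(object, k = min(20L, nrow(object)), ...) {
  keep <- top_variance_nodes(object, k)
  long <- tidy(object) |>
    dplyr::filter(.data$node %in% keep) |>
    dplyr::mutate(node = factor(.data$node, levels = rev(keep)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$patient_id, y = .data$node,
                                     fill = .data$contribution)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "Patient", y = "Hidden node",
                  title = "Node contributions to the prognostic index") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}
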