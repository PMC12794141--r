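#' @title Diagnostic plots
#' @description ggplot2 autoplot methods for the package's result objects.
#' @name plots
NULL

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_errorbar geom_line
#'   geom_point labs theme_minimal facet_wrap coord_flip
#' @export
ggplot2::autoplot

#' @describeIn mp_channel_importance ranked bar chart of per-channel loss
#'   increases (error bars: sd across evaluation folds).
#' @param object an `mp_importance` tibble.
#' @param ... unused.
#' @method autoplot mp_importance
#' @export
autoplot.mp_importance <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(channel = stats::reorder(.data$channel, .data$mean_dloss))
  ggplot(d, aes(x = .data$channel, y = .data$mean_dloss)) +
    geom_col(fill = "steelblue") +
    geom_errorbar(aes(ymin = .data$mean_dloss - .data$sd_dloss,
                      ymax = .data$mean_dloss + .data$sd_dloss),
                  width = 0.3, na.rm = TRUE) +
    coord_flip() +
    labs(x = NULL, y = expression(Delta * "loss (masked - unmasked)"),
         title = "Node-feature-channel importance") +
    theme_minimal()
}

#' @describeIn mp_cross_validate per-fold metric values.
#' @param object an `mp_metric_report`.
#' @param ... unused.
#' @method autoplot mp_metric_report
#' @export
autoplot.mp_metric_report <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_fold, -"fold", names_to = "metric")
  ggplot(d, aes(x = factor(.data$fold), y = .data$value)) +
    geom_point(color = "steelblue", na.rm = TRUE) +
    facet_wrap(~ .data$metric, scales = "free_y") +
    labs(x = "fold", y = NULL, title = "Cross-validation metrics") +
    theme_minimal()
}

#' @describeIn mp_fit_classifier training and validation loss curves.
#' @param object a fitted `macro_pp`.
#' @param ... unused.
#' @method autoplot macro_pp
#' @export
autoplot.macro_pp <- function(object, ...) {
  d <- tidyr::pivot_longer(object$log, -"epoch", names_to = "series")
  ggplot(d, aes(x = .data$epoch, y = .data$value, color = .data$series)) +
    geom_line() +
    labs(x = "epoch", y = "loss", color = NULL,
         title = sprintf("Training curves (%s)", object$task)) +
    theme_minimal()
}

#' @describeIn mp_cluster_fidelity 2D embedding colored by cluster.
#' @param object an `mp_cluster`.
#' @param ... unused.
#' @method autoplot mp_cluster
#' @export
autoplot.mp_cluster <- function(object, ...) {
  d <- tibble(x = object$embedding[, 1], y = object$embedding[, 2],
              cluster = factor(object$assignment))
  ggplot(d, aes(x = .data$x, y = .data$y, color = .data$cluster)) +
    geom_point() +
    labs(title = sprintf("High-fidelity clusters (k = %d, %s)",
                         object$n_clusters, object$chosen_by)) +
    theme_minimal()
}
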