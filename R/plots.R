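#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a prefix-metrics report
#'
#' Bootstrap mean with the 95% (or configured) percentile interval per metric
#' and depth.
#'
#' @param object An `ec_metrics` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ec_metrics
#' @export
autoplot.ec_metrics <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$depth), y = .data$boot_mean,
                                   colour = .data$metric, group = .data$metric)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower,
                                          ymax = .data$ci_upper),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "EC prefix depth", y = "Bootstrap mean (95% CI)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a training log
#'
#' Total loss and its instance/exemplar components per epoch; distance-map
#' refresh epochs are marked.
#'
#' @param object A `hince_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hince_fit
#' @export
autoplot.hince_fit <- function(object, ...) {
  df <- object$log |>
    tidyr::pivot_longer(c("loss", "instance", "exemplar"),
                        names_to = "term", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$log$epoch[object$log$refreshed],
                        linetype = "dotted", colour = "grey60") +
    ggplot2::labs(x = "Epoch", y = "Mean batch loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot label-frequency statistics
#'
#' Histogram of sequences per EC4 class and a bar chart of per-EC1 totals.
#'
#' @param object An `ec_stats` object from [compute_dataset_stats()].
#' @param ... Unused.
#' @return A ggplot object (two panels via facetting on summary type).
#' @method autoplot ec_stats
#' @export
autoplot.ec_stats <- function(object, ...) {
  df <- dplyr::bind_rows(
    object$per_ec4 |>
      dplyr::count(.data$n, name = "count") |>
      dplyr::transmute(panel = "sequences per EC4 class",
                       x = as.character(.data$n), y = .data$count),
    object$per_ec1 |>
      dplyr::transmute(panel = "sequences per EC1 class",
                       x = .data$ec1, y = .data$n)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = "count") +
    ggplot2::theme_minimal()
}
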