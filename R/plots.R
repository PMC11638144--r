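#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot real-parameter estimates of a fitted model
#'
#' Point estimates with 95% intervals on the probability scale, one row per
#' real parameter (area-specific survivals, change probability, initial
#' distribution, recapture, device functioning).
#'
#' @param object A `cmr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cmr_fit <- function(object, ...) {
  d <- object$real
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "estimate (probability scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a QAICc model-comparison table
#'
#' @param object A `cmr_model_table` from [run_model_set()].
#' @param ... Unused.
#' @return A ggplot object showing Akaike weights by model.
#' @export
autoplot.cmr_model_table <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$model <- factor(d$model, levels = rev(d$model))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$weight, y = .data$model)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "QAICc weight", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-area track counts of a fidelity summary
#'
#' @param object A `fidelity_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fidelity_summary <- function(object, ...) {
  ggplot2::ggplot(object$area_counts,
                  ggplot2::aes(x = .data$area, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "wintering area", y = "tracks") +
    ggplot2::theme_minimal()
}
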