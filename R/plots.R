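# ggplot2 views of comparison results.

#' Boxplot of an input indicator across median-split output groups
#'
#' The batch-level view of the input/output relationship: prescriptions
#' are split at the median of an output indicator (e.g. DeDT) and an input
#' indicator (e.g. Dedis) is drawn per group.
#'
#' @param panels Indicator table from [batch_indicators()].
#' @param outcome Unquoted output column to split on (default `dedt`).
#' @param input Unquoted input column to draw (default `dedis`).
#' @param labels Group labels, low then high.
#'
#' @return A ggplot object.
#' @export
plot_indicator_groups <- function(panels, outcome = dedt, input = dedis,
                                  labels = c("low", "high")) {
  split <- median_split(panels, {{ outcome }}, labels = labels)
  cut <- attr(split, "split_value")
  ggplot2::ggplot(split, ggplot2::aes(.data$group, {{ input }})) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 1) +
    ggplot2::labs(
      x = sprintf(
        "%s group (median cutoff %.3g)",
        rlang::as_name(rlang::enquo(outcome)), cut
      ),
      y = rlang::as_name(rlang::enquo(input))
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of a prescription's indicator panel
#'
#' @param object A `dose_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dose_comparison <- function(object, ...) {
  long <- tidy(object)
  long <- long[!is.na(long$value), ]
  long$indicator <- factor(long$indicator, levels = long$indicator)
  ggplot2::ggplot(long, ggplot2::aes(.data$indicator, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "indicator value") +
    ggplot2::theme_minimal()
}

#' Weighted degree distribution per network layer
#'
#' @param object A `prescription_network`.
#' @param ... Unused.
#' @return A ggplot object (boxplot of weighted degree by layer).
#' @export
autoplot.prescription_network <- function(object, ...) {
  deg <- weighted_degree(object)
  ggplot2::ggplot(
    deg,
    ggplot2::aes(
      factor(.data$layer,
        levels = c("drug", "metabolite", "target", "disease")
      ),
      .data$degree
    )
  ) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "layer", y = "weighted degree") +
    ggplot2::theme_minimal()
}
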