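#' Plot the proportion of "normal" judgments with the estimated norm range
#'
#' Draws the per-size proportion of participants (or repetitions) judging
#' each portion normal, the majority criterion line, and the estimated
#' norm-range span, faceted by food.
#'
#' @param judgments Normality judgment tibble.
#' @param ranges Norm-range tibble for the same judgments.
#' @param threshold Majority criterion drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_norm_ranges <- function(judgments, ranges, threshold = 0.6) {
  props <- judgments |>
    dplyr::summarise(prop = mean(.data$response), .by = c("food_id", "size"))
  valid <- dplyr::filter(ranges, .data$valid)
  ggplot2::ggplot(props, ggplot2::aes(x = .data$size, y = .data$prop)) +
    ggplot2::geom_rect(
      data = valid,
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "steelblue", alpha = 0.15
    ) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$food_id)) +
    ggplot2::labs(x = "Portion size (% of reference)",
                  y = "Proportion judged 'normal'") +
    ggplot2::theme_minimal()
}

#' Plot intended consumption by portion-size category
#'
#' Sample means with standard-error bars per food and category, with the
#' Likert midpoint marked: above the line means the whole portion plus more,
#' below it only part of the portion.
#'
#' @param means Output of [category_means()].
#' @param midpoint Likert midpoint reference line. Default 4.
#' @return A ggplot object.
#' @export
plot_category_means <- function(means, midpoint = 4) {
  summ <- means |>
    dplyr::summarise(
      m = mean(.data$mean_rating),
      se = stats::sd(.data$mean_rating) / sqrt(dplyr::n()),
      .by = c("food_id", "category")
    )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$category, y = .data$m)) +
    ggplot2::geom_hline(yintercept = midpoint, linetype = "dashed") +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$m - .data$se, ymax = .data$m + .data$se),
      width = 0.2
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$food_id)) +
    ggplot2::scale_y_continuous(limits = c(0, 7)) +
    ggplot2::labs(x = "Portion-size category", y = "Intended consumption (1-7)") +
    ggplot2::theme_minimal()
}

#' Plot discrimination performance by boundary category
#'
#' @param x An `nr_boundary_perf` object from [performance_by_boundary()].
#' @param measure `"accuracy"` or `"rt"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.nr_boundary_perf <- function(x, measure = c("accuracy", "rt"), ...) {
  measure <- match.arg(measure)
  col <- if (measure == "accuracy") "accuracy" else "mean_rt"
  summ <- x$means |>
    dplyr::summarise(
      m = mean(.data[[col]], na.rm = TRUE),
      se = stats::sd(.data[[col]], na.rm = TRUE) / sqrt(dplyr::n()),
      .by = c("food_id", "boundary_category")
    )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$boundary_category, y = .data$m)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$m - .data$se, ymax = .data$m + .data$se),
      width = 0.2
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$food_id)) +
    ggplot2::labs(x = "Pair position in norm range",
                  y = if (measure == "accuracy") "Proportion correct"
                      else "Mean correct-trial RT (ms)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
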