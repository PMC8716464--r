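#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a power-budget sweep
#'
#' Two stacked panels over the sweep's power budgets (log10 x-axis): the
#' envelope at the target with the half-value focality, and the per-source
#' total injected currents with the grand-optimal point marked — the usual
#' way the amplitude-focality trade-off and the grand-optimal selection are
#' displayed.
#'
#' @param object A `sweep_result` from [sweep_pmax()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  df <- tidy.sweep_result(object)
  df <- dplyr::filter(df, .data$valid)
  long <- dplyr::bind_rows(
    tibble::tibble(exponent = df$exponent, panel = "envelope at target (V/m)",
                   series = "envelope", value = df$envelope_target,
                   grand_optimal = df$grand_optimal),
    tibble::tibble(exponent = df$exponent, panel = "focality F (cm)",
                   series = "F", value = df$focality_cm,
                   grand_optimal = df$grand_optimal),
    tibble::tibble(exponent = df$exponent, panel = "total current (mA)",
                   series = "sum |s1|", value = df$sum_abs_s1,
                   grand_optimal = df$grand_optimal),
    tibble::tibble(exponent = df$exponent, panel = "total current (mA)",
                   series = "sum |s2|", value = df$sum_abs_s2,
                   grand_optimal = df$grand_optimal)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$exponent, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = dplyr::filter(long, .data$grand_optimal),
                        shape = 0, size = 4, colour = "black") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = expression(log[10](P[max] / P[max0])), y = NULL,
                  colour = NULL,
                  title = "Power-budget sweep",
                  subtitle = "square marks the grand-optimal point") +
    ggplot2::theme_minimal()
}

#' Plot an epicranial-vs-transcranial comparison table
#'
#' Dodged bars of the grand-optimal envelope at the target and the
#' half-value focality, per target and condition.
#'
#' @param object A `comparison_table` from [run_comparison()] (or any
#'   tibble with `target`, `condition`, `e_target`, `focality_cm`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.comparison_table <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(target = object$target, condition = object$condition,
                   metric = "envelope at target (V/m)", value = object$e_target),
    tibble::tibble(target = object$target, condition = object$condition,
                   metric = "focality F (cm)", value = object$focality_cm)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$target, y = .data$value,
                                     fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = "Interferential montage comparison") +
    ggplot2::theme_minimal()
}
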