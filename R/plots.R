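#' Plot tensile curves
#'
#' Stress-strain curves coloured by orientation, one line per specimen.
#'
#' @param curves Tidy curve tibble.
#' @return A ggplot.
#' @export
plot_curves <- function(curves) {
  check_curve_table(curves)
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$strain, y = .data$stress_kpa,
                               colour = .data$orientation,
                               group = .data$specimen_id)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "nominal strain (-)", y = "nominal stress (kPa)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a calibrated fit against the pooled mean curves
#'
#' Points are the orientation mean curves the model was fitted to; lines are
#' the model prediction at the fitted parameters.
#'
#' @param object A `fibrelast_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fibrelast_fit <- function(object, ...) {
  ggplot2::ggplot(object$mean_curves,
                  ggplot2::aes(x = .data$strain, colour = .data$orientation)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$stress_kpa), size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred)) +
    ggplot2::labs(
      title = paste0(object$model_name, " fit (",
                     sprintf("RMSE %.1f%% / %.1f%%", object$rmse_circ,
                             object$rmse_long), ")"),
      x = "nominal strain (-)", y = "nominal stress (kPa)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a model comparison as a percent-RMSE bar chart
#'
#' @param object A `fibrelast_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fibrelast_comparison <- function(object, ...) {
  long <- object$report |>
    dplyr::filter(!.data$failed) |>
    tidyr::pivot_longer(c("rmse_circ_pct", "rmse_long_pct"),
                        names_to = "orientation", values_to = "rmse_pct") |>
    dplyr::mutate(orientation = ifelse(
      .data$orientation == "rmse_circ_pct", "circumferential",
      "longitudinal"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$model, y = .data$rmse_pct,
                               fill = .data$orientation)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "RMSE (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
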