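#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a glucose/insulin/meal timeline
#'
#' CGM and true glucose traces with the eu-glycaemic band (70-180 mg/dL),
#' meal carbohydrates as bars, and the commanded basal rate.
#'
#' @param object A `meal_timeline`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meal_timeline <- function(object, ...) {
  long <- object |>
    dplyr::transmute(time_h = .data$time_min / 60,
                     CGM = .data$cgm_mgdl, `true BG` = .data$true_bg_mgdl) |>
    tidyr::pivot_longer(-"time_h", names_to = "series",
                        values_to = "mgdl")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$mgdl,
                                     colour = .data$series)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 70, ymax = 180,
                      alpha = 0.08, fill = "seagreen") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (h)", y = "glucose (mg/dL)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot training history of a forecaster
#'
#' @param object A `qseq2seq` bundle.
#' @param ... Unused.
#' @return A ggplot object of training and validation loss per epoch.
#' @export
autoplot.qseq2seq <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                              names_to = "split", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::labs(x = "epoch", y = "total pinball loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Control-variability grid plot
#'
#' CVGA scatter of per-subject (minimum BG, maximum BG) points on the
#' standard nine-zone grid.  The x axis (minimum BG) is reversed so control
#' quality worsens away from the lower-left A zone.
#'
#' @param points A tibble of [cvga_point()] rows, optionally with extra
#'   grouping columns mapped via `colour`.
#' @param colour Optional column name (string) to colour points by, e.g. a
#'   controller configuration.
#' @return A ggplot object.
#' @export
plot_cvga <- function(points, colour = NULL) {
  p <- ggplot2::ggplot(points, ggplot2::aes(x = .data$min_bg,
                                            y = .data$max_bg))
  for (v in c(70, 90)) {
    p <- p + ggplot2::geom_vline(xintercept = v, colour = "grey70")
  }
  for (h in c(180, 300)) {
    p <- p + ggplot2::geom_hline(yintercept = h, colour = "grey70")
  }
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                                 size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::scale_x_reverse(limits = c(110, 50)) +
    ggplot2::scale_y_continuous(limits = c(110, 400)) +
    ggplot2::labs(x = "minimum BG (mg/dL)", y = "maximum BG (mg/dL)") +
    ggplot2::theme_minimal()
}
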