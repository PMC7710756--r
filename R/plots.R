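#' Plot a position-time matrix
#'
#' Heatmap with time on the x axis and position (pixels along the spread
#' axis) on the y axis; a propagating wave appears as a sloped ridge. An
#' optional [fit_speed()] result overlays the regression line and its speed.
#'
#' @param object a `position_time_plot`.
#' @param fit optional `ridge_fit`.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.position_time_plot <- function(object, fit = NULL, ...) {
  df <- as_tibble.position_time_plot(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$position_px)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_viridis_c(name = object$signal) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time (s)",
                  y = sprintf("%s position (px)", object$axis),
                  title = sprintf("%s, %s hemisphere", object$signal,
                                  object$hemisphere)) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    tr <- range(fit$points$time)
    seg <- tibble::tibble(
      x = tr[1], xend = tr[2],
      y = fit$intercept_px + fit$slope_px_per_s * tr[1],
      yend = fit$intercept_px + fit$slope_px_per_s * tr[2])
    p <- p +
      ggplot2::geom_segment(data = seg,
                            ggplot2::aes(x = .data$x, xend = .data$xend,
                                         y = .data$y, yend = .data$yend),
                            colour = "white", linewidth = 0.8) +
      ggplot2::annotate("label", x = mean(tr),
                        y = fit$intercept_px + fit$slope_px_per_s * mean(tr),
                        label = sprintf("%.2f mm/min", fit$speed_mm_min),
                        size = 3)
  }
  p
}

#' Plot a sliding-window EEG power series
#'
#' @param object a `power_series` from [total_power_series()].
#' @param events optional LVA event tibble to shade.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.power_series <- function(object, events = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$time, .data$power)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "time (s)", y = "total power (uV^2, 0.5-100 Hz)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events))
    p <- p + ggplot2::geom_rect(
      data = tibble::as_tibble(events),
      ggplot2::aes(xmin = .data$onset, xmax = .data$offset,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.2)
  p
}

#' Raster of LVA events across subjects
#'
#' One horizontal lane per subject; each event drawn as a segment coloured by
#' laterality.
#'
#' @param events tibble with `subject`, `onset`, `offset` and optionally
#'   `laterality`.
#' @return A ggplot object.
#' @export
plot_event_raster <- function(events) {
  ev <- tibble::as_tibble(events)
  if (!"laterality" %in% names(ev)) ev$laterality <- "event"
  ggplot2::ggplot(ev) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$onset / 3600, xend = .data$offset / 3600,
                   y = .data$subject, yend = .data$subject,
                   colour = .data$laterality),
      linewidth = 4) +
    ggplot2::labs(x = "time (h)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
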