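#' Plot spatial coding accuracy against speed
#'
#' @param object an [sca()] result (possibly several row-bound, e.g. original
#'   and shuffled).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sca_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$speed, y = .data$accuracy,
    colour = ifelse(.data$shuffled, "shuffled", "original"))) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::labs(x = "speed bin", y = "spatial coding accuracy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot metric-versus-speed observations with a BLEA predictive band
#'
#' @param table data frame with columns `dataset_id`, `speed`, `value`.
#' @param ens optional [ensemble()] posterior; when supplied, the posterior
#'   mean line and 95% predictive band are overlaid.
#' @return a ggplot object.
#' @export
plot_metric_speed <- function(table, ens = NULL) {
  p <- ggplot2::ggplot(table, ggplot2::aes(x = .data$speed, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(x = "speed", y = "metric value") +
    ggplot2::theme_minimal()
  if (!is.null(ens)) {
    vg <- seq(min(table$speed), max(table$speed), length.out = 50)
    band <- predictive_interval(ens, vg)
    p <- p +
      ggplot2::geom_ribbon(
        data = band,
        ggplot2::aes(x = .data$v, ymin = .data$lo, ymax = .data$hi),
        inherit.aes = FALSE, alpha = 0.2) +
      ggplot2::geom_line(
        data = band, ggplot2::aes(x = .data$v, y = .data$mean),
        inherit.aes = FALSE)
  }
  p
}

#' Plot a spatial rate map
#'
#' @param map a [rate_map()].
#' @return a ggplot object.
#' @export
plot_rate_map <- function(map) {
  xc <- (map$x_edges[-1] + map$x_edges[-length(map$x_edges)]) / 2
  yc <- (map$y_edges[-1] + map$y_edges[-length(map$y_edges)]) / 2
  df2 <- tibble::tibble(
    x = rep(xc, times = length(yc)),
    y = rep(yc, each = length(xc)),
    rate = as.vector(map$map)
  )
  ggplot2::ggplot(df2, ggplot2::aes(.data$x, .data$y, fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", fill = "Hz") +
    ggplot2::theme_minimal()
}
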