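#' Plot sector density series with outbreak windows
#'
#' Annual sector COTS density with the threshold ladder as horizontal
#' guides and detected outbreak windows shaded.
#'
#' @param series Sector series, see [sector_density_series()].
#' @param outbreaks Optional windows from [detect_outbreaks()].
#' @param config A [threshold_config()] supplying the guide levels.
#' @return A ggplot object.
#' @export
plot_sector_series <- function(series, outbreaks = NULL,
                               config = threshold_config()) {
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$year, y = .data$density))
  if (!is.null(outbreaks) && nrow(outbreaks) > 0) {
    p <- p + ggplot2::geom_rect(
      data = outbreaks,
      ggplot2::aes(xmin = .data$start_year, xmax = .data$end_year),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "firebrick", alpha = 0.12
    )
  }
  p +
    ggplot2::geom_hline(yintercept = c(config$potential, config$established),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::geom_hline(yintercept = config$severe, linetype = "dashed",
                        colour = "grey30") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$imputed), size = 1.8) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::facet_wrap(~sector_id) +
    ggplot2::labs(x = "Year", y = "COTS per tow", shape = "Interpolated") +
    ggplot2::theme_minimal()
}

interval_plot <- function(df, xvar) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data$median)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$ci90_lo, ymax = .data$ci90_hi),
                            linewidth = 0.4) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$ci66_lo, ymax = .data$ci66_hi),
                            linewidth = 1.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::theme_minimal()
}

#' Plot methods for fitted objects
#'
#' `autoplot()` draws posterior medians with 66% (thick) and 90% (thin)
#' credible bars for the Bayesian fits, and fitted curves with 95% bands
#' for the trajectory smoother.
#'
#' @param object A fitted object from this package.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-cots
NULL

#' @rdname autoplot-cots
#' @export
autoplot.cots_cover_fit <- function(object, ...) {
  ggplot2::ggplot(object$summaries,
                  ggplot2::aes(x = .data$year, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci90_lo, ymax = .data$ci90_hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~sector_id) +
    ggplot2::labs(x = "Year", y = "Hard coral cover (proportion)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-cots
#' @export
autoplot.cots_wave_fit <- function(object, ...) {
  cells <- object$summaries[object$summaries$type == "cell", ]
  interval_plot(cells, "wave") +
    ggplot2::facet_wrap(~sector_id) +
    ggplot2::labs(x = "Outbreak wave",
                  y = if (object$response == "density") "COTS per tow"
                      else "Relative cover change (%)")
}

#' @rdname autoplot-cots
#' @export
autoplot.cots_effort_fit <- function(object, ...) {
  interval_plot(object$summaries, "category") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Culling-effort stratum",
                  y = "Annual cover change (pp/yr)")
}

#' @rdname autoplot-cots
#' @export
autoplot.cots_gam_fit <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$years_since_onset, y = .data$fit)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "Years since outbreak onset",
                  y = "Relative cover change (%)") +
    ggplot2::theme_minimal()
}
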