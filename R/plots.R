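#' Plot a resistance map
#'
#' Tile plot of the per-bin mean relative blockade over channel
#' coordinates — darker tiles are higher local resistance.
#'
#' @param object A `resistance_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.resistance_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x_c, .data$y_c,
                                       fill = .data$mean_a)) +
    ggplot2::geom_tile(width = attr(object, "bin_um"),
                       height = attr(object, "bin_um")) +
    ggplot2::scale_fill_distiller(palette = "Reds", direction = 1,
                                  name = expression(Delta * I / I[p])) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(x[c] ~ (mu * m)),
                  y = expression(y[c] ~ (mu * m)),
                  title = "Channel resistance map") +
    ggplot2::theme_minimal()
}

#' Plot an axial amplitude profile
#'
#' Moving-average blockade versus axial position with a ±1 sd band; the
#' dashed verticals mark the channel entrance and exit.
#'
#' @param object An `axial_profile`.
#' @param L Channel length (µm) for the entrance/exit guides; taken from
#'   the profile's `x_max` context if missing.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.axial_profile <- function(object, L = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$x_c, .data$mean_a)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_a - .data$sd_a,
                                      ymax = .data$mean_a + .data$sd_a),
                         fill = "red", alpha = 0.2) +
    ggplot2::geom_line(colour = "red") +
    ggplot2::labs(x = expression(x[c] ~ (mu * m)),
                  y = expression(Delta * I / I[p]),
                  title = "Axial amplitude profile") +
    ggplot2::theme_minimal()
  if (!is.null(L)) {
    p <- p + ggplot2::geom_vline(xintercept = c(0, L), linetype = "dashed")
  }
  p
}

#' Scatter plot of event amplitude versus duration with the linear fit
#'
#' @param events Event table from [region_amplitudes()].
#' @param fit Optional [amp_duration_fit()] result to overlay.
#' @return A ggplot.
#' @export
plot_amp_duration <- function(events, fit = NULL) {
  p <- ggplot2::ggplot(events, ggplot2::aes(.data$duration_s * 1e3,
                                            .data$amplitude)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "event duration (ms)", y = expression(Delta * I / I[p]),
                  title = "Amplitude versus duration") +
    ggplot2::theme_minimal()
  if (!is.null(fit) && !isTRUE(fit$degenerate)) {
    p <- p + ggplot2::geom_abline(intercept = fit$intercept,
                                  slope = fit$slope / 1e3,
                                  linetype = "dashed")
  }
  p
}

#' Histogram of wide/narrow amplitude ratios with the theory line
#'
#' @param object A `ratio_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ratio_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$ratio)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = attr(object, "theory"),
                        linetype = "dashed") +
    ggplot2::labs(x = "wide / narrow amplitude ratio", y = "events",
                  title = "Cavity versus narrow blockade ratios") +
    ggplot2::theme_minimal()
}

#' Plot lateral-position profiles
#'
#' @param x A `lateral_stats` object.
#' @param which `"duration"` or `"amplitude"`.
#' @return A ggplot.
#' @export
plot_lateral <- function(x, which = c("duration", "amplitude")) {
  which <- match.arg(which)
  prof <- if (which == "duration") x$profile_duration else x$profile_amplitude
  ev <- x$events
  yval <- if (which == "duration") ev$duration_s else ev$amplitude
  ggplot2::ggplot() +
    ggplot2::geom_point(data = ev,
                        ggplot2::aes(.data$y_mean_um, !!rlang::sym(
                          if (which == "duration") "duration_s" else "amplitude")),
                        alpha = 0.3) +
    ggplot2::geom_line(data = prof, ggplot2::aes(.data$y_bin, .data$mean),
                       colour = "white", linewidth = 1) +
    ggplot2::geom_line(data = prof,
                       ggplot2::aes(.data$y_bin, .data$mean + .data$sd),
                       colour = "white", linetype = "dashed") +
    ggplot2::geom_line(data = prof,
                       ggplot2::aes(.data$y_bin, .data$mean - .data$sd),
                       colour = "white", linetype = "dashed") +
    ggplot2::labs(x = expression(y[c] ~ (mu * m)),
                  y = if (which == "duration") "duration (s)"
                  else expression(Delta * I / I[p])) +
    ggplot2::theme_dark()
}
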