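# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_path geom_errorbar
#'   geom_vline geom_abline labs theme_minimal
NULL

#' Plot recorded simulation trajectories
#'
#' @param object A `lane_sim` run with `record = "trajectories"`.
#' @param max_tracks Number of tracks to draw (longest first).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lane_sim <- function(object, max_tracks = 30, ...) {
  if (is.null(object$tracks))
    stop_bad_input("autoplot.lane_sim: simulate with record = 'trajectories'")
  keep <- object$tracks |>
    dplyr::count(.data$track_id, sort = TRUE) |>
    head(max_tracks)
  df <- dplyr::semi_join(object$tracks, keep, by = "track_id")
  ggplot(df, aes(x = .data$x_um, y = .data$y_um, group = .data$track_id,
                 colour = .data$track_id)) +
    geom_path(alpha = 0.7, show.legend = FALSE) +
    labs(x = "x (µm)", y = "y (µm)",
         title = sprintf("Simulated tracks, lane width %g µm",
                         object$config$lane$width)) +
    theme_minimal()
}

#' Plot mean displacement versus lag time with the drift fit
#'
#' @param object A `drift_estimate`.
#' @param ... Unused.
#' @export
autoplot.drift_estimate <- function(object, ...) {
  ggplot(object$lag_means, aes(x = .data$tau_s, y = .data$mean_dx)) +
    geom_point() +
    geom_abline(intercept = object$intercept, slope = object$v_d,
                colour = "red") +
    labs(x = expression(n * Delta * t ~ "(s)"),
         y = expression(paste("<", Delta * x, "> (", mu, "m)")),
         title = sprintf("Drift velocity %.2f µm/s", object$v_d)) +
    theme_minimal()
}

#' Plot a drift-vs-width sweep
#'
#' @param object A `width_sweep`.
#' @param ... Unused.
#' @export
autoplot.width_sweep <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$width, y = .data$v_d)) +
    geom_errorbar(aes(ymin = .data$v_d - .data$sem,
                      ymax = .data$v_d + .data$sem), width = 0.3) +
    geom_line() + geom_point() +
    geom_vline(xintercept = object$peak_width, linetype = 2, colour = "red") +
    labs(x = "lane width (µm)", y = "drift velocity (µm/s)",
         title = sprintf("r = %g µm; peak width %.2f µm",
                         object$radius, object$peak_width)) +
    theme_minimal()
}

#' Plot the optimal-width versus radius law
#'
#' @param object A `radius_sweep`.
#' @param ... Unused.
#' @export
autoplot.radius_sweep <- function(object, ...) {
  ggplot(object$peaks, aes(x = .data$radius, y = .data$peak_width)) +
    geom_point(size = 2) +
    geom_abline(intercept = 0, slope = object$slope, colour = "red") +
    labs(x = "circling radius r (µm)", y = "optimal lane width (µm)",
         title = sprintf("w = k r, k = %.3f ± %.3f",
                         object$slope, object$slope_sd)) +
    theme_minimal()
}

#' Plot the closed-form collision probability with optional MC checks
#'
#' @param curve Output of [geometry_curve()].
#' @param mc Optional tibble from [mc_first_collision()] calls
#'   (rows bound together) drawn as points with error bars.
#' @return A ggplot.
#' @export
plot_geometry_curve <- function(curve = geometry_curve(), mc = NULL) {
  p <- ggplot(curve, aes(x = .data$m, y = .data$p)) +
    geom_line() +
    labs(x = "m = w / r", y = "P(first contact RSW, up-gradient)") +
    theme_minimal()
  if (!is.null(mc)) {
    p <- p + geom_point(data = mc, aes(y = .data$p_hat), colour = "red") +
      geom_errorbar(data = mc,
                    aes(y = .data$p_hat, ymin = .data$p_hat - 2 * .data$se,
                        ymax = .data$p_hat + 2 * .data$se),
                    colour = "red", width = 0.02)
  }
  p
}
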