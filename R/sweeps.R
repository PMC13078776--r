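# Width and radius sweep drivers: drift velocity vs lane width for one
# circling radius, and the peak-width ~ radius law across radii.

#' Gaussian peak of a drift-vs-width curve
#'
#' Fits `v = A exp(-(w - mu)^2 / (2 sigma^2))` to the grid points around the
#' peak (the three largest drift values and their immediate neighbors) and
#' returns the fitted peak location `mu`. Falls back to the raw argmax with
#' a warning when the fit does not converge.
#'
#' @param width Grid of widths (um).
#' @param v_d Drift velocity at each width (um/s).
#' @return A list with `peak` (um), `method` (`"gaussian"` or `"argmax"`),
#'   and the `fit` object (or NULL).
#' @export
fit_gaussian_peak <- function(width, v_d) {
  if (length(width) < 3) stop_bad_input("fit_gaussian_peak: need >= 3 grid points")
  ord <- order(width)
  width <- width[ord]; v_d <- v_d[ord]
  top <- order(v_d, decreasing = TRUE)[seq_len(min(3, length(v_d)))]
  keep <- sort(unique(pmin(pmax(c(top - 1, top, top + 1), 1), length(width))))
  df <- tibble(w = width[keep], v = v_d[keep])
  i0 <- which.max(v_d)
  start <- list(A = max(v_d), mu = width[i0],
                sigma = max(diff(range(width[keep])) / 3, 0.5))
  fit <- try(minpack.lm::nlsLM(
    v ~ A * exp(-(w - mu)^2 / (2 * sigma^2)), data = df, start = start,
    lower = c(A = 0, mu = min(width), sigma = 1e-3),
    upper = c(A = Inf, mu = max(width), sigma = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error") || !is.finite(coef(fit)[["mu"]])) {
    warning("fit_gaussian_peak: Gaussian fit failed; using raw argmax")
    return(list(peak = width[i0], method = "argmax", fit = NULL))
  }
  list(peak = unname(coef(fit)[["mu"]]), method = "gaussian", fit = fit)
}

#' Drift velocity across lane widths
#'
#' Runs [simulate_lane()] at each width (same radius and gradient) and
#' summarizes drift with its SEM over repeats, the raw argmax width, and
#' the Gaussian-fit peak width.
#'
#' @param widths Lane widths to simulate (um), at least 3.
#' @param radius Circular-swimming radius (um).
#' @param n_cells,duration,reps,seed Passed to [simulate_lane()]; each
#'   width runs with an independent seed derived from `seed`.
#' @param lane_template A [lane_config()] supplying length/gradient; its
#'   width field is replaced per sweep point.
#' @param motility A [motility_params()]; its radius is replaced.
#' @param ... Further arguments to [simulate_lane()].
#' @return An object of class `width_sweep`: tibble `$curve`
#'   (width, v_d, sem), `$argmax_width`, `$peak_width` (Gaussian),
#'   `$radius`.
#' @export
sweep_width <- function(widths, radius = 10, n_cells = 100, duration = 150,
                        reps = 50, seed = NULL,
                        lane_template = lane_config(width = 8),
                        motility = motility_params(), ...) {
  if (length(widths) < 3) stop_bad_input("sweep_width: need at least 3 widths")
  motility$radius <- radius
  seeds <- if (is.null(seed)) rep(list(NULL), length(widths))
           else as.list(seed + seq_along(widths) - 1L)
  rows <- purrr::map2(widths, seeds, function(w, s) {
    lane <- lane_config(width = w, length = lane_template$length,
                        grad_slope = lane_template$grad_slope,
                        c_intercept = lane_template$c_intercept)
    sim <- simulate_lane(lane, motility = motility, n_cells = n_cells,
                         duration = duration, reps = reps, seed = s, ...)
    tibble(width = w, v_d = sim$v_d, sem = sim$sem)
  })
  curve <- dplyr::bind_rows(rows)
  pk <- fit_gaussian_peak(curve$width, curve$v_d)
  structure(list(curve = curve,
                 argmax_width = curve$width[which.max(curve$v_d)],
                 peak_width = pk$peak, peak_method = pk$method,
                 radius = radius),
            class = "width_sweep")
}

#' @export
print.width_sweep <- function(x, ...) {
  cat(sprintf("Width sweep at r = %g um (%d widths)\n", x$radius, nrow(x$curve)))
  cat(sprintf("  argmax width %g um; Gaussian peak %.2f um (%s)\n",
              x$argmax_width, x$peak_width, x$peak_method))
  invisible(x)
}

#' @export
tidy.width_sweep <- function(x, ...) x$curve

#' @export
glance.width_sweep <- function(x, ...) {
  tibble(radius = x$radius, argmax_width = x$argmax_width,
         peak_width = x$peak_width, peak_method = x$peak_method)
}

default_width_grid <- function(radius) {
  seq(max(2, round(0.3 * radius)), round(1.5 * radius), by = 1)
}

#' Optimal-width versus radius law
#'
#' For each circling radius, sweeps a width grid spanning
#' `[0.3 r, 1.5 r]` (1 um resolution by default), extracts the
#' drift-maximizing width by Gaussian peak fit, then fits the
#' origin-constrained law `w_peak = k r` by least squares.
#'
#' @param radii Circling radii (um), at least 3 distinct values.
#' @param width_grid Function mapping a radius to its width grid.
#' @inheritParams sweep_width
#' @return An object of class `radius_sweep`: `$peaks` (radius, peak
#'   width, argmax), `$slope` k with `$slope_sd`, and all width curves in
#'   `$curves`.
#' @export
sweep_radius <- function(radii = c(5, 7.5, 10, 12.5, 15),
                         width_grid = default_width_grid,
                         n_cells = 100, duration = 150, reps = 20,
                         seed = NULL, lane_template = lane_config(width = 8),
                         motility = motility_params(), ...) {
  if (length(unique(radii)) < 3)
    stop_bad_input("sweep_radius: need at least 3 distinct radii")
  sweeps <- purrr::imap(radii, function(r, i) {
    s <- if (is.null(seed)) NULL else seed + 1000L * i
    sweep_width(width_grid(r), radius = r, n_cells = n_cells,
                duration = duration, reps = reps, seed = s,
                lane_template = lane_template, motility = motility, ...)
  })
  peaks <- dplyr::bind_rows(lapply(sweeps, glance))
  # least squares through the origin: k = sum(w r) / sum(r^2)
  k <- sum(peaks$peak_width * peaks$radius) / sum(peaks$radius^2)
  resid <- peaks$peak_width - k * peaks$radius
  k_sd <- sqrt(sum(resid^2) / (nrow(peaks) - 1) / sum(peaks$radius^2))
  curves <- dplyr::bind_rows(lapply(sweeps, function(s)
    dplyr::mutate(s$curve, radius = s$radius)))
  structure(list(peaks = peaks, slope = k, slope_sd = k_sd, curves = curves),
            class = "radius_sweep")
}

#' @export
print.radius_sweep <- function(x, ...) {
  cat(sprintf("Radius sweep (%d radii): peak width = k * r with k = %.3f +/- %.3f\n",
              nrow(x$peaks), x$slope, x$slope_sd))
  invisible(x)
}

#' @export
tidy.radius_sweep <- function(x, ...) x$peaks

#' @export
glance.radius_sweep <- function(x, ...) {
  tibble(slope = x$slope, slope_sd = x$slope_sd, n_radii = nrow(x$peaks))
}
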