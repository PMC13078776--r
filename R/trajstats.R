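# Trajectory statistics applied identically to particle-tracking exports
# and simulator output. A track table has columns
# track_id, time_s, x_um, y_um (frame optional), uniformly sampled in time.

validate_tracks <- function(tracks) {
  need <- c("track_id", "time_s", "x_um", "y_um")
  missing_cols <- setdiff(need, names(tracks))
  if (length(missing_cols) > 0)
    stop_bad_input(paste0("track table must have columns ",
                          paste(need, collapse = ", "),
                          "; missing: ", paste(missing_cols, collapse = ", ")))
  invisible(tracks)
}

track_dt <- function(time_s) {
  d <- diff(time_s)
  if (length(d) == 0) return(NA_real_)
  if (max(d) - min(d) > 1e-6)
    stop_bad_input("track frames must be uniformly spaced in time (within 1e-6 s)")
  d[1]
}

#' Per-frame velocity by the fourth-order central difference
#'
#' `v_i = (8 (p_{i+1} - p_{i-1}) - (p_{i+2} - p_{i-2})) / (12 dt)` per
#' coordinate; exact for positions that are polynomials in time up to
#' degree 4. The first and last two frames of each track are excluded.
#'
#' @param tracks A track table (`track_id, time_s, x_um, y_um`); tracks with
#'   fewer than 5 frames raise an error.
#' @return A tibble with `track_id`, `frame` (position within track,
#'   0-based), `time_s`, `vx`, `vy`, `speed`, and `heading` (rad, from
#'   `atan2(vy, vx)`).
#' @export
track_velocity <- function(tracks) {
  validate_tracks(tracks)
  stencil <- function(p, dt) {
    nf <- length(p)
    i <- 3:(nf - 2)
    (8 * (p[i + 1] - p[i - 1]) - (p[i + 2] - p[i - 2])) / (12 * dt)
  }
  parts <- lapply(split(seq_len(nrow(tracks)), tracks$track_id), function(rows) {
    nf <- length(rows)
    if (nf < 5)
      stop_bad_input("track_velocity: each track needs at least 5 frames")
    t_s <- tracks$time_s[rows]
    dt <- track_dt(t_s)
    vx <- stencil(tracks$x_um[rows], dt)
    vy <- stencil(tracks$y_um[rows], dt)
    tibble(track_id = tracks$track_id[rows][3:(nf - 2)],
           frame = (3:(nf - 2)) - 1L,
           time_s = t_s[3:(nf - 2)],
           vx = vx, vy = vy,
           speed = sqrt(vx^2 + vy^2),
           heading = atan2(vy, vx))
  })
  dplyr::bind_rows(parts)
}

#' Mean swimming speed per track
#'
#' The speed of a trajectory is the average of the per-frame velocity
#' magnitudes over interior frames.
#'
#' @inheritParams track_velocity
#' @return A tibble with `track_id` and `speed` (um/s).
#' @export
track_speed <- function(tracks) {
  track_velocity(tracks) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(speed = mean(.data$speed), .groups = "drop")
}

#' Chemotactic drift velocity by lag regression
#'
#' For each lag `n`, the mean x-displacement `<x(i+n) - x(i)>` is pooled
#' over all valid frame pairs of all tracks, then regressed on the lag time
#' `n dt` by ordinary least squares (with intercept); the slope is the drift
#' velocity. Tracks shorter than a lag simply contribute nothing at that
#' lag, which makes the estimator insensitive to tracks that end early
#' (e.g. cells lost by the tracker or recycled at an x boundary).
#'
#' @inheritParams track_velocity
#' @param lags Frame lags to use (default odd lags 1, 3, ..., 39).
#' @param dt Frame interval (s); inferred from `time_s` when `NULL`.
#' @return An object of class `drift_estimate`: `v_d` (slope, um/s), `sd`
#'   (standard error of the slope), `intercept` (um), `lags_used`,
#'   `lag_means` (pooled mean displacement per lag), `n_tracks`.
#' @export
drift_velocity <- function(tracks, lags = seq(1L, 39L, by = 2L), dt = NULL) {
  validate_tracks(tracks)
  xs <- split(tracks$x_um, tracks$track_id)
  if (is.null(dt)) {
    ts1 <- split(tracks$time_s, tracks$track_id)
    dts <- vapply(ts1, track_dt, numeric(1))
    dt <- stats::median(dts, na.rm = TRUE)
  }
  sums <- numeric(length(lags))
  counts <- numeric(length(lags))
  for (p in xs) {
    nf <- length(p)
    cp <- cumsum(p)
    for (k in seq_along(lags)) {
      nlg <- lags[k]
      if (nf <= nlg) next
      s_last <- cp[nf] - if (nf - nlg >= 1) cp[nf - nlg] else 0
      s_first <- cp[nlg]
      sums[k] <- sums[k] + (s_last - s_first)
      counts[k] <- counts[k] + (nf - nlg)
    }
  }
  ok <- counts > 0
  if (sum(ok) < 2)
    stop_bad_input("drift_velocity: not enough frame pairs at the requested lags")
  md <- sums[ok] / counts[ok]
  tau <- lags[ok] * dt
  fit <- lm(md ~ tau)
  est <- summary(fit)$coefficients
  structure(list(
    v_d = unname(est["tau", "Estimate"]),
    sd = unname(est["tau", "Std. Error"]),
    intercept = unname(est["(Intercept)", "Estimate"]),
    lags_used = lags[ok],
    lag_means = tibble(lag = lags[ok], tau_s = tau, mean_dx = md,
                       n_pairs = counts[ok]),
    n_tracks = length(xs),
    dt = dt
  ), class = "drift_estimate")
}

#' @export
print.drift_estimate <- function(x, ...) {
  cat(sprintf("Drift velocity: %.3f um/s (slope SE %.3f, intercept %.3f um)\n",
              x$v_d, x$sd, x$intercept))
  cat(sprintf("  %d tracks, lags %d..%d frames, dt = %g s\n",
              x$n_tracks, min(x$lags_used), max(x$lags_used), x$dt))
  invisible(x)
}

#' @export
tidy.drift_estimate <- function(x, ...) {
  tibble(term = c("v_d", "intercept"),
         estimate = c(x$v_d, x$intercept),
         std.error = c(x$sd, NA_real_))
}

#' @export
glance.drift_estimate <- function(x, ...) {
  tibble(v_d = x$v_d, sd = x$sd, intercept = x$intercept,
         n_tracks = x$n_tracks, n_lags = length(x$lags_used))
}

#' Mean-squared orientational displacement of one track
#'
#' `MSOD(tau) = <(theta(t + tau) - theta(t))^2>` with heading differences
#' wrapped to `(-pi, pi]`, for lag times `tau = k dt < tau_max`. Headings
#' come from the central-difference velocity direction; frames slower than
#' `min_speed` are excluded (direction is ill-defined near zero velocity).
#'
#' @param traj A single-track table.
#' @param tau_max Largest lag time (s), exclusive.
#' @param min_speed Speed floor (um/s) for defining a heading.
#' @return A tibble with `tau_s`, `msod` (rad^2), `n_pairs`.
#' @export
msod <- function(traj, tau_max = 0.4, min_speed = 1) {
  v <- track_velocity(traj)
  if (length(unique(v$track_id)) != 1)
    stop_bad_input("msod: provide a single track")
  dt <- track_dt(v$time_s)
  theta <- ifelse(v$speed >= min_speed, v$heading, NA_real_)
  kmax <- max(1L, ceiling(tau_max / dt) - 1L)
  ks <- seq_len(kmax)
  ks <- ks[ks * dt < tau_max]
  if (length(ks) == 0 || length(theta) < 2)
    stop_bad_input("msod: track too short for the requested tau_max")
  rows <- lapply(ks, function(k) {
    if (length(theta) <= k) return(NULL)
    d <- wrap_angle(theta[-seq_len(k)] - theta[seq_len(length(theta) - k)])
    d <- d[!is.na(d)]
    if (length(d) == 0) return(NULL)
    tibble(tau_s = k * dt, msod = mean(d^2), n_pairs = length(d))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    stop_bad_input("msod: no valid heading pairs (speeds below min_speed?)")
  out
}

#' Rotational exponent from an MSOD curve
#'
#' Fits `MSOD = C_R tau^gamma_R` by least squares in log-log space. The
#' exponent separates canonical motions: ~0 for straight wall-aligned
#' swimming, ~1 for rotational diffusion, ~2 for circular swimming. Tracks
#' whose MSOD is uniformly below `floor` (straight tracks up to numerical
#' noise) return `gamma_r = 0` by convention.
#'
#' @param msod_curve Output of [msod()] (needs >= 3 points), or a
#'   single-track table (the curve is computed with defaults).
#' @param floor MSOD floor (rad^2) under which a track counts as straight.
#' @return An object of class `rotational_fit` with `c_r`, `gamma_r`.
#' @export
rotational_exponent <- function(msod_curve, floor = 1e-12) {
  if (!("msod" %in% names(msod_curve)) && "x_um" %in% names(msod_curve))
    msod_curve <- msod(msod_curve)
  if (all(msod_curve$msod < floor))
    return(structure(list(c_r = 0, gamma_r = 0, n = nrow(msod_curve)),
                     class = "rotational_fit"))
  cur <- msod_curve[msod_curve$msod > floor, ]
  if (nrow(cur) < 3)
    stop_bad_input("rotational_exponent: need at least 3 positive MSOD points")
  fit <- lm(log(msod) ~ log(tau_s), data = cur)
  structure(list(c_r = exp(unname(coef(fit)[1])),
                 gamma_r = unname(coef(fit)[2]),
                 n = nrow(cur)),
            class = "rotational_fit")
}

#' @export
print.rotational_fit <- function(x, ...) {
  cat(sprintf("MSOD power law: gamma_R = %.3f, C_R = %.4g rad^2/s^gamma\n",
              x$gamma_r, x$c_r))
  invisible(x)
}

#' @export
tidy.rotational_fit <- function(x, ...) {
  tibble(term = c("gamma_r", "c_r"), estimate = c(x$gamma_r, x$c_r))
}

#' Rotational exponents for a collection of tracks
#'
#' @inheritParams track_velocity
#' @inheritParams msod
#' @return A tibble with `track_id`, `gamma_r`, `c_r`, `mean_y`.
#' @export
track_rotational_exponents <- function(tracks, tau_max = 0.4, min_speed = 1) {
  validate_tracks(tracks)
  idx <- split(seq_len(nrow(tracks)), tracks$track_id)
  parts <- lapply(idx, function(rows) {
    tr <- tibble(track_id = tracks$track_id[rows[1]],
                 time_s = tracks$time_s[rows],
                 x_um = tracks$x_um[rows], y_um = tracks$y_um[rows])
    fit <- try(rotational_exponent(msod(tr, tau_max, min_speed)), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    tibble(track_id = tr$track_id[1], gamma_r = fit$gamma_r, c_r = fit$c_r,
           mean_y = mean(tr$y_um))
  })
  dplyr::bind_rows(parts)
}

#' Detect tumbles from the per-frame speed
#'
#' A tumble is a maximal run of at least 2 consecutive frames whose speed
#' lies below the track-average speed `<v>`, provided the event shows a
#' substantial drop: at least one successive speed decrease within the event
#' (including the entry drop from the frame preceding it) exceeds
#' `<v> * alpha`. Isolated one-frame dips are not tumbles.
#'
#' @param traj A single-track table.
#' @param alpha Drop threshold as a fraction of the mean speed.
#' @return A tibble of events: `start_frame`, `end_frame` (0-based frame
#'   numbers), `n_frames`, `duration_s`, and `angle_rad`, the wrapped
#'   heading change from the frame before the event to the frame after it
#'   (NA when the event touches the ends of the speed series).
#' @export
detect_tumbles <- function(traj, alpha = 1 / 6) {
  v <- track_velocity(traj)
  if (length(unique(v$track_id)) != 1)
    stop_bad_input("detect_tumbles: provide a single track")
  dt <- track_dt(v$time_s)
  ev <- tumble_events_from_speed(v$speed, alpha)
  if (nrow(ev) == 0)
    return(tibble(start_frame = integer(0), end_frame = integer(0),
                  n_frames = integer(0), duration_s = numeric(0),
                  angle_rad = numeric(0)))
  angle <- ifelse(ev$start > 1L & ev$end < nrow(v),
                  wrap_angle(v$heading[pmin(ev$end + 1L, nrow(v))] -
                               v$heading[pmax(ev$start - 1L, 1L)]),
                  NA_real_)
  tibble(start_frame = v$frame[ev$start], end_frame = v$frame[ev$end],
         n_frames = ev$end - ev$start + 1L,
         duration_s = (ev$end - ev$start + 1L) * dt,
         angle_rad = angle)
}

# Event logic on a bare speed series: maximal runs of >= 2 consecutive
# below-mean frames with at least one successive drop (entry drop included)
# exceeding mean(speed) * alpha. Returns start/end indices into the series.
tumble_events_from_speed <- function(speed, alpha = 1 / 6) {
  vbar <- mean(speed)
  rl <- rle(speed < vbar)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- logical(length(rl$values))
  for (i in which(rl$values & rl$lengths >= 2L)) {
    drop_idx <- max(starts[i] - 1L, 1L):(ends[i] - 1L)
    keep[i] <- max(speed[drop_idx] - speed[drop_idx + 1L]) > vbar * alpha
  }
  tibble(start = starts[keep], end = ends[keep])
}

#' Algebraic (Kasa) circle fit
#'
#' Positions are smoothed with a Savitzky-Golay filter (window
#' `smooth_window`, polynomial order `sg_order`), then the linear system
#' `x^2 + y^2 = 2 a x + 2 b y + c` is solved by least squares; the radius is
#' `sqrt(c + a^2 + b^2)`. Intended for curved (middle-area) tracks; gate
#' candidates with [track_rotational_exponents()] at `gamma_r > 1.6` when
#' reproducing the surface-swimming radius distribution.
#'
#' @param traj A single-track table with at least `smooth_window` frames.
#' @param smooth_window Savitzky-Golay window size (odd).
#' @param sg_order Savitzky-Golay polynomial order.
#' @param smooth Set `FALSE` to fit the raw positions.
#' @return An object of class `circle_fit` with `center` (um), `radius`
#'   (um), `residual` (rms radial misfit, um), `n`.
#' @export
fit_circle <- function(traj, smooth_window = 5, sg_order = 2, smooth = TRUE) {
  validate_tracks(traj)
  x <- traj$x_um
  y <- traj$y_um
  if (length(x) < (if (smooth) max(5, smooth_window) else 3))
    stop_bad_input("fit_circle: track too short")
  if (smooth) {
    x <- signal::sgolayfilt(x, p = sg_order, n = smooth_window)
    y <- signal::sgolayfilt(y, p = sg_order, n = smooth_window)
  }
  A <- cbind(x, y, 1)
  qa <- qr(A)
  if (qa$rank < 3)
    stop_bad_input("fit_circle: degenerate geometry (collinear points)")
  coefs <- qr.coef(qa, x^2 + y^2)
  a <- coefs[1] / 2
  b <- coefs[2] / 2
  r2 <- coefs[3] + a^2 + b^2
  if (!is.finite(r2) || r2 <= 0)
    stop_bad_input("fit_circle: degenerate geometry (non-positive radius)")
  r <- sqrt(r2)
  resid <- sqrt(mean((sqrt((x - a)^2 + (y - b)^2) - r)^2))
  structure(list(center = c(x = unname(a), y = unname(b)),
                 radius = unname(r), residual = resid, n = length(x)),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("Circle fit: center (%.2f, %.2f) um, radius %.3f um, rms residual %.3g um\n",
              x$center[1], x$center[2], x$radius, x$residual))
  invisible(x)
}

#' @export
tidy.circle_fit <- function(x, ...) {
  tibble(term = c("center_x", "center_y", "radius"),
         estimate = c(unname(x$center[1]), unname(x$center[2]), x$radius))
}

#' Classify tracks into sidewall and middle regions
#'
#' By mean transverse position: LSW (left sidewall) for `<y> <= d`, RSW
#' (right sidewall) for `<y> >= w - d`, MA (middle area) otherwise; boundary
#' values go to the walls. The default threshold d = 3 um is about one cell
#' body length.
#'
#' @inheritParams track_velocity
#' @param lane_width Lane width w (um).
#' @param d Wall threshold (um).
#' @return A tibble with `track_id`, `mean_y`, `region` (factor LSW/MA/RSW).
#' @export
classify_region <- function(tracks, lane_width, d = 3) {
  validate_tracks(tracks)
  if (lane_width <= 0) stop_bad_input("classify_region: lane_width must be positive")
  if (lane_width <= 2 * d)
    warning("classify_region: lane_width <= 2 d; the MA region is empty")
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(mean_y = mean(.data$y_um), .groups = "drop") |>
    dplyr::mutate(region = factor(
      dplyr::case_when(
        .data$mean_y <= d ~ "LSW",
        .data$mean_y >= lane_width - d ~ "RSW",
        TRUE ~ "MA"
      ),
      levels = c("LSW", "MA", "RSW")
    ))
}

#' Region occupancy proportions
#'
#' @inheritParams classify_region
#' @return A tibble with one row per region: `n` tracks and `prop`
#'   (fractions sum to 1).
#' @export
region_proportions <- function(tracks, lane_width, d = 3) {
  cls <- classify_region(tracks, lane_width, d)
  cls |>
    dplyr::count(.data$region, .drop = FALSE) |>
    dplyr::mutate(prop = .data$n / sum(.data$n))
}

#' Up- vs down-gradient split of right-sidewall tracks
#'
#' Among RSW-classified tracks, a track counts as up-gradient when its net
#' x displacement is positive (operational definition; the mean x-velocity
#' sign gives the same answer for essentially all wall-aligned tracks).
#'
#' @inheritParams classify_region
#' @return A tibble with `direction` (`up`, `down`), `n`, `prop`.
#' @export
rsw_direction_split <- function(tracks, lane_width, d = 3) {
  cls <- classify_region(tracks, lane_width, d)
  rsw_ids <- cls$track_id[cls$region == "RSW"]
  if (length(rsw_ids) == 0)
    stop_bad_input("rsw_direction_split: no RSW tracks")
  net <- tracks |>
    dplyr::filter(.data$track_id %in% rsw_ids) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(net_dx = dplyr::last(.data$x_um) - dplyr::first(.data$x_um),
                     .groups = "drop")
  tibble(direction = c("up", "down"),
         n = c(sum(net$net_dx > 0), sum(net$net_dx <= 0))) |>
    dplyr::mutate(prop = .data$n / sum(.data$n))
}
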