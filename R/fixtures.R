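# Synthetic trajectory generators with known ground truth. They emulate
# 20 fps particle-tracking exports (track table schema) so every statistic
# can be validated without experimental data; the generating parameters are
# stored in the "ground_truth" attribute.

fixture_track <- function(track_id, t_s, x, y, noise_sd, truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd < 0) stop_bad_input("noise_sd must be >= 0")
  if (noise_sd > 0) {
    x <- x + rnorm(length(x), 0, noise_sd)
    y <- y + rnorm(length(y), 0, noise_sd)
  }
  out <- tibble(track_id = track_id, frame = seq_along(t_s) - 1L,
                time_s = t_s, x_um = x, y_um = y)
  attr(out, "ground_truth") <- truth
  out
}

#' Ground truth of a synthetic track
#'
#' @param traj A fixture track (or ensemble).
#' @return The generating-parameter list.
#' @export
ground_truth <- function(traj) attr(traj, "ground_truth")

#' Straight synthetic track
#'
#' Constant-velocity motion plus optional isotropic Gaussian position noise
#' (tracking-jitter proxy; 0.1 um is sub-pixel at typical 20x optics).
#'
#' @param speed Speed (um/s), >= 0.
#' @param heading Heading (rad).
#' @param n_frames Number of frames (>= 5).
#' @param dt Frame interval (s).
#' @param noise_sd Positional noise SD (um).
#' @param x0,y0 Start position (um).
#' @param track_id Track identifier.
#' @param seed Optional seed.
#' @return A track tibble with a `ground_truth` attribute.
#' @export
make_straight <- function(speed, heading = 0, n_frames = 200, dt = 0.05,
                          noise_sd = 0.1, x0 = 0, y0 = 0,
                          track_id = "straight-1", seed = NULL) {
  if (speed < 0) stop_bad_input("make_straight: speed must be >= 0")
  if (n_frames < 5) stop_bad_input("make_straight: need >= 5 frames")
  t_s <- (seq_len(n_frames) - 1L) * dt
  fixture_track(track_id, t_s,
                x0 + speed * cos(heading) * t_s,
                y0 + speed * sin(heading) * t_s,
                noise_sd,
                list(kind = "straight", speed = speed, heading = heading,
                     dt = dt, noise_sd = noise_sd),
                seed)
}

#' Circular synthetic track
#'
#' Uniform circular motion at the simulator's chirality (heading angle
#' increasing for `chirality = 1`), the ground truth for surface-swimming
#' radius measurements.
#'
#' @param radius Circle radius (um), positive.
#' @param speed Speed (um/s), positive.
#' @param chirality +1 or -1 turn direction.
#' @param cx,cy Circle center (um).
#' @param phase0 Initial phase angle on the circle (rad).
#' @inheritParams make_straight
#' @export
make_circular <- function(radius, speed = 20, n_frames = 400, dt = 0.05,
                          noise_sd = 0.1, chirality = 1, cx = 0, cy = 0,
                          phase0 = 0, track_id = "circle-1", seed = NULL) {
  if (radius <= 0 || speed <= 0)
    stop_bad_input("make_circular: radius and speed must be positive")
  if (n_frames < 5) stop_bad_input("make_circular: need >= 5 frames")
  t_s <- (seq_len(n_frames) - 1L) * dt
  psi <- phase0 + chirality * (speed / radius) * t_s
  fixture_track(track_id, t_s,
                cx + radius * cos(psi), cy + radius * sin(psi),
                noise_sd,
                list(kind = "circular", radius = radius, speed = speed,
                     chirality = chirality, dt = dt, noise_sd = noise_sd),
                seed)
}

#' Run-and-tumble synthetic track
#'
#' Alternates constant-speed straight runs (exponential durations at
#' `run_rate`) with stationary tumbles (exit rate `exit_rate`, so 0.2 s mean
#' at the default 5 s^-1) whose signed angles come from the
#' truncated-exponential model. The event log (tumble start/end frames and
#' applied angles) is kept in the ground truth for oracle comparisons.
#'
#' @param run_rate Run-to-tumble rate (s^-1), positive.
#' @param tumble_angle_b Characteristic tumble angle (rad).
#' @param duration Track duration (s).
#' @param speed Run speed (um/s).
#' @param exit_rate Tumble-to-run rate (s^-1).
#' @inheritParams make_straight
#' @export
make_run_tumble <- function(run_rate, tumble_angle_b = 1.35, duration = 500,
                            dt = 0.05, speed = 20, exit_rate = 5,
                            noise_sd = 0, track_id = "runtumble-1",
                            seed = NULL) {
  if (run_rate < 0 || exit_rate <= 0 || speed <= 0)
    stop_bad_input("make_run_tumble: rates and speed must be positive (run_rate >= 0)")
  if (!is.null(seed)) set.seed(seed)
  n_frames <- round(duration / dt) + 1L
  model <- tumble_angle_model(tumble_angle_b)
  x <- numeric(n_frames); y <- numeric(n_frames)
  th <- runif(1, -pi, pi)
  tumbling <- FALSE
  log_start <- integer(0); log_end <- integer(0); log_angle <- numeric(0)
  t_start <- NA_integer_
  for (i in 2:n_frames) {
    if (!tumbling) {
      if (run_rate > 0 && runif(1) < run_rate * dt) {
        tumbling <- TRUE
        t_start <- i - 1L
        x[i] <- x[i - 1]; y[i] <- y[i - 1]
        next
      }
      x[i] <- x[i - 1] + speed * cos(th) * dt
      y[i] <- y[i - 1] + speed * sin(th) * dt
    } else {
      if (runif(1) < exit_rate * dt) {
        ang <- sample_tumble_angle(1, model)
        th <- wrap_angle(th + ang)
        log_start <- c(log_start, t_start)
        log_end <- c(log_end, i - 1L)
        log_angle <- c(log_angle, ang)
        tumbling <- FALSE
        x[i] <- x[i - 1] + speed * cos(th) * dt
        y[i] <- y[i - 1] + speed * sin(th) * dt
      } else {
        x[i] <- x[i - 1]; y[i] <- y[i - 1]
      }
    }
  }
  t_s <- (seq_len(n_frames) - 1L) * dt
  fixture_track(track_id, t_s, x, y, noise_sd,
                list(kind = "run_tumble", run_rate = run_rate,
                     tumble_angle_b = tumble_angle_b, speed = speed,
                     exit_rate = exit_rate, dt = dt, noise_sd = noise_sd,
                     events = tibble(start_frame = log_start,
                                     end_frame = log_end,
                                     angle = log_angle)),
                seed = NULL)
}

#' Ensemble of drifting noisy tracks
#'
#' Straight tracks along +x at a known drift speed with positional noise:
#' the generator truth for the lag-regression drift estimator.
#'
#' @param n_tracks Number of tracks.
#' @param drift Drift speed (um/s).
#' @inheritParams make_straight
#' @export
make_drift_ensemble <- function(n_tracks = 50, drift = 1.6, n_frames = 120,
                                dt = 0.05, noise_sd = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- dplyr::bind_rows(lapply(seq_len(n_tracks), function(i) {
    make_straight(speed = drift, heading = 0, n_frames = n_frames, dt = dt,
                  noise_sd = noise_sd, x0 = runif(1, 0, 100),
                  y0 = runif(1, 0, 40), track_id = paste0("drift-", i))
  }))
  attr(out, "ground_truth") <- list(kind = "drift_ensemble", drift = drift,
                                    n_tracks = n_tracks, noise_sd = noise_sd)
  out
}

#' Ensemble realizing exact region proportions
#'
#' Places straight tracks at fixed transverse positions (1 um inside each
#' wall threshold, mid-lane for MA) so that [region_proportions()] recovers
#' the requested fractions exactly.
#'
#' @param proportions Length-3 numeric (LSW, MA, RSW), summing to 1;
#'   `proportions * n_tracks` must be whole numbers.
#' @param lane_width Lane width (um); must exceed `2 d` when an MA fraction
#'   is requested.
#' @param n_tracks Total number of tracks.
#' @param d Wall threshold (um).
#' @inheritParams make_straight
#' @export
make_region_ensemble <- function(proportions, lane_width, n_tracks = 100,
                                 d = 3, n_frames = 60, dt = 0.05,
                                 noise_sd = 0, seed = NULL) {
  if (length(proportions) != 3 || abs(sum(proportions) - 1) > 1e-8)
    stop_bad_input("make_region_ensemble: proportions must be length 3 and sum to 1")
  counts <- proportions * n_tracks
  if (any(abs(counts - round(counts)) > 1e-8))
    stop_bad_input("make_region_ensemble: proportions * n_tracks must be whole numbers")
  counts <- round(counts)
  if (lane_width <= 2 * d && counts[2] > 0)
    stop_bad_input("make_region_ensemble: no MA region exists for lane_width <= 2 d")
  if (!is.null(seed)) set.seed(seed)
  ys <- c(rep(min(d - 1, d / 2), counts[1]),
          rep(lane_width / 2, counts[2]),
          rep(lane_width - min(d - 1, d / 2), counts[3]))
  out <- dplyr::bind_rows(lapply(seq_along(ys), function(i) {
    make_straight(speed = 15, heading = 0, n_frames = n_frames, dt = dt,
                  noise_sd = noise_sd, x0 = 0, y0 = ys[i],
                  track_id = paste0("region-", i))
  }))
  attr(out, "ground_truth") <- list(kind = "region_ensemble",
                                    proportions = proportions,
                                    lane_width = lane_width, d = d)
  out
}
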