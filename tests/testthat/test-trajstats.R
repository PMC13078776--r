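# Trajectory statistics on tracks with known ground truth.

test_that("central-difference velocity is exact for low-order polynomials", {
  lin <- track_from_fun(function(t) 2 * t, function(t) 0 * t, 50)
  v <- track_velocity(lin)
  expect_equal(v$vx, rep(2, nrow(v)))
  expect_equal(v$vy, rep(0, nrow(v)))
  # the 5-point stencil differentiates cubics exactly
  cub <- track_from_fun(function(t) t^3, function(t) 0 * t, 50)
  vc <- track_velocity(cub)
  expect_equal(vc$vx, 3 * vc$time_s^2, tolerance = 1e-10)
  stat <- track_from_fun(function(t) rep(5, length(t)), function(t) rep(1, length(t)), 20)
  expect_equal(track_velocity(stat)$speed, rep(0, 16))
  short <- track_from_fun(function(t) t, function(t) t, 4)
  expect_error(track_velocity(short), "5 frames")
})

test_that("trajectory speed matches the parameterization", {
  expect_equal(track_speed(make_straight(2, 0, noise_sd = 0))$speed, 2)
  circ <- make_circular(10, speed = 20, noise_sd = 0)
  expect_equal(track_speed(circ)$speed, 20, tolerance = 0.005)
})

test_that("lag regression recovers drift and rejects closed orbits", {
  ens <- make_drift_ensemble(n_tracks = 60, drift = 1.6, n_frames = 120,
                             noise_sd = 0.5, seed = 5)
  est <- drift_velocity(ens)
  expect_equal(est$v_d, 1.6, tolerance = 0.05 * 1.6)

  still <- dplyr::bind_rows(lapply(1:10, function(i)
    make_straight(0, 0, n_frames = 80, noise_sd = 0.3, x0 = i,
                  track_id = paste0("s", i), seed = i)))
  expect_lt(abs(drift_velocity(still)$v_d), 0.1)

  orbits <- dplyr::bind_rows(lapply(1:6, function(i)
    make_circular(10, n_frames = 380, noise_sd = 0, cx = 10 * i,
                  phase0 = i, track_id = paste0("c", i))))
  expect_lt(abs(drift_velocity(orbits)$v_d), 0.25)

  # tracks shorter than a lag just drop out of that lag
  mixed <- dplyr::bind_rows(ens, make_straight(1.6, 0, n_frames = 10,
                                               noise_sd = 0.5,
                                               track_id = "tiny", seed = 1))
  expect_equal(drift_velocity(mixed)$v_d, est$v_d, tolerance = 0.05)
  # a 3-frame track supports only lag 1: not enough lags to regress
  stub <- tibble::tibble(track_id = "x", time_s = c(0, 0.05, 0.1),
                         x_um = c(0, 1, 2), y_um = 0)
  expect_error(drift_velocity(stub), "lags")
})

test_that("MSOD separates constant, diffusive, and circular heading motion", {
  circ <- make_circular(10, speed = 20, n_frames = 200, noise_sd = 0)
  cur <- msod(circ)
  omega <- 20 / 10
  expect_equal(cur$msod, omega^2 * cur$tau_s^2, tolerance = 0.01)
  expect_equal(rotational_exponent(cur)$gamma_r, 2, tolerance = 0.05)

  straight <- make_straight(20, pi / 5, n_frames = 200, noise_sd = 0)
  expect_equal(max(msod(straight)$msod), 0, tolerance = 1e-12)
  expect_identical(rotational_exponent(msod(straight))$gamma_r, 0)

  brown <- brownian_heading_track(d_rot = 0.3, n_frames = 4000, seed = 3)
  fit <- rotational_exponent(msod(brown))
  expect_equal(fit$gamma_r, 1, tolerance = 0.25)
})

test_that("tumble events require two below-mean frames and a substantial drop", {
  # hand-traced series: mean 13, alpha threshold 13/6
  ev <- lanetaxis:::tumble_events_from_speed(c(20, 20, 3, 2, 20))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, 3)
  expect_equal(ev$end, 4)
  # single-frame dips are not tumbles (n >= 2)
  expect_equal(nrow(lanetaxis:::tumble_events_from_speed(c(20, 20, 3, 20))), 0)
  # constant speed: nothing below the mean
  expect_equal(nrow(lanetaxis:::tumble_events_from_speed(rep(10, 8))), 0)
  # two below-mean frames without any drop beyond <v>/6 do not qualify
  expect_equal(nrow(lanetaxis:::tumble_events_from_speed(c(10, 10, 9.5, 9.4, 10))), 0)
})

test_that("tumble detection closes the loop with the run-tumble generator", {
  rt <- make_run_tumble(run_rate = 0.5, tumble_angle_b = 1.35,
                        duration = 500, seed = 8)
  truth <- ground_truth(rt)$events
  found <- detect_tumbles(rt)
  expect_gt(nrow(found), 0)
  expect_equal(nrow(found), nrow(truth), tolerance = 0.2)
  b_hat <- fit_tumble_angles(abs(found$angle_rad[!is.na(found$angle_rad)]),
                             method = "mle")
  expect_equal(b_hat$b, 1.35, tolerance = 0.15 * 1.35)
  # no tumbles when the run never ends
  quiet <- make_run_tumble(run_rate = 0, duration = 60, seed = 9)
  expect_equal(nrow(detect_tumbles(quiet)), 0)
})

test_that("the algebraic circle fit is exact on circles and rejects lines", {
  pts <- tibble::tibble(track_id = "q", time_s = (0:3) * 0.05,
                        x_um = c(5, 0, -5, 0), y_um = c(0, 5, 0, -5))
  fit <- fit_circle(pts, smooth = FALSE)
  expect_equal(unname(fit$center), c(0, 0), tolerance = 1e-10)
  expect_equal(fit$radius, 5, tolerance = 1e-10)

  arc <- make_circular(10, n_frames = 120, noise_sd = 0)  # ~3/4 turn
  expect_equal(fit_circle(arc, smooth = FALSE)$radius, 10, tolerance = 1e-6)
  expect_equal(fit_circle(arc)$radius, 10, tolerance = 0.02)

  noisy <- make_circular(10, n_frames = 200, noise_sd = 0.2, seed = 4)
  expect_equal(fit_circle(noisy)$radius, 10, tolerance = 0.05)

  line <- make_straight(10, pi / 7, n_frames = 30, noise_sd = 0)
  expect_error(fit_circle(line, smooth = FALSE), "degenerate")
})

test_that("region classification uses the stated boundary inequalities", {
  mk <- function(y, id) make_straight(15, 0, n_frames = 20, noise_sd = 0,
                                      y0 = y, track_id = id)
  tracks <- dplyr::bind_rows(mk(2, "a"), mk(42, "b"), mk(22, "c"),
                             mk(3, "d"), mk(41, "e"))
  cls <- classify_region(tracks, 44)
  expect_equal(as.character(cls$region[match(c("a", "b", "c", "d", "e"),
                                             cls$track_id)]),
               c("LSW", "RSW", "MA", "LSW", "RSW"))  # boundaries go to walls
  expect_warning(classify_region(tracks, 5), "MA")
})

test_that("region proportions and the RSW split match constructed ensembles", {
  ens <- make_region_ensemble(c(0.20, 0.59, 0.21), lane_width = 44,
                              n_tracks = 100)
  pr <- region_proportions(ens, 44)
  expect_equal(pr$prop, c(0.20, 0.59, 0.21))
  expect_equal(sum(pr$prop), 1)

  all_ma <- make_region_ensemble(c(0, 1, 0), 44, n_tracks = 10)
  expect_equal(region_proportions(all_ma, 44)$prop, c(0, 1, 0))
  expect_error(make_region_ensemble(c(0.2, 0.6, 0.2), 5, n_tracks = 10), "MA")

  up <- dplyr::bind_rows(lapply(1:4, function(i)
    make_straight(15, 0, y0 = 43, noise_sd = 0, track_id = paste0("u", i))))
  expect_equal(rsw_direction_split(up, 44)$prop, c(1, 0))
  mirrored <- dplyr::bind_rows(up,
    dplyr::bind_rows(lapply(1:4, function(i)
      make_straight(15, pi, x0 = 120, y0 = 43, noise_sd = 0,
                    track_id = paste0("d", i)))))
  expect_equal(rsw_direction_split(mirrored, 44)$prop, c(0.5, 0.5))
})
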