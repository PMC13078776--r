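# Lane simulator: kinematics, wall rules, boundary recycling, determinism.

no_tumble_pathway <- pathway_params(hill_k = 1e6)  # B ~ 0: pure running

test_that("configuration objects validate their invariants", {
  expect_error(lane_config(width = -1), "positive")
  expect_error(lane_config(width = 8, grad_slope = -1), "non-negative")
  expect_error(motility_params(dt = 0), "positive")
  expect_error(motility_params(chirality = 2), "chirality")
  expect_error(simulate_lane(lane_config(width = 8), duration = 0.01), "duration")
})

test_that("the linear attractant profile is clipped to the lane", {
  lane <- lane_config(width = 8)
  expect_equal(concentration_at(0, lane), 22)
  expect_equal(concentration_at(160, lane), 30)
  expect_equal(concentration_at(-5, lane), 22)
  expect_equal(concentration_at(1000, lane), 30)
  lane0 <- lane_config(width = 8, grad_slope = 0)
  expect_equal(concentration_at(100, lane0), 22)
})

test_that("sidewall collisions clamp, align, and tie-break toward +x", {
  hit <- wall_collision(y = 8.4, theta = pi / 4, width = 8)
  expect_equal(hit$y, 8)
  expect_equal(hit$theta, 0)
  expect_equal(hit$on_wall, 2L)
  expect_equal(wall_collision(8.4, 3 * pi / 4, 8)$theta, pi)
  # exactly perpendicular hit goes to +x by convention
  expect_equal(wall_collision(8.4, pi / 2, 8)$theta, 0)
  bot <- wall_collision(-0.3, -pi / 4, 8)
  expect_equal(bot$y, 0)
  expect_equal(bot$theta, 0)
  expect_equal(bot$on_wall, 1L)
  # interior positions untouched
  free <- wall_collision(4, 1, 8)
  expect_equal(free$on_wall, 0L)
  expect_equal(free$theta, 1)
})

test_that("x boundary wraps periodically", {
  lane <- lane_config(width = 8)
  expect_equal(wrap_x(161, lane), 1)
  expect_equal(wrap_x(-2, lane), 158)
  expect_equal(wrap_x(42, lane), 42)
})

test_that("identical seeds give bit-identical simulations", {
  run <- function() simulate_lane(lane_config(width = 10), n_cells = 10,
                                  duration = 20, reps = 2,
                                  record = c("episodes", "trajectories"),
                                  seed = 99)
  a <- run(); b <- run()
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$drift, b$drift)
  expect_identical(a$episodes, b$episodes)
})

test_that("cells stay confined to the lane at every recorded frame", {
  sim <- simulate_lane(lane_config(width = 6), n_cells = 30, duration = 40,
                       reps = 2, record = "trajectories", seed = 7)
  expect_true(all(sim$tracks$y_um >= 0 & sim$tracks$y_um <= 6))
  expect_true(all(sim$tracks$x_um >= 0 & sim$tracks$x_um <= 160))
})

test_that("tumble-free runs trace circles of the configured radius", {
  sim <- simulate_lane(lane_config(width = 100, length = 1000),
                       motility_params(radius = 10, d_rot = 0),
                       pathway = no_tumble_pathway,
                       n_cells = 4, duration = 10, reps = 1,
                       record = "trajectories", seed = 21)
  tr <- split(sim$tracks, sim$tracks$track_id)
  checked <- 0
  for (t1 in tr) {
    if (nrow(t1) < 100) next
    if (min(t1$y_um) <= 0 || max(t1$y_um) >= 100) next  # touched a wall
    fit <- fit_circle(t1, smooth = FALSE)
    expect_equal(fit$radius, 10, tolerance = 0.02)
    checked <- checked + 1
  }
  expect_gte(checked, 2)
})

test_that("the curvature term vanishes as the swimming radius diverges", {
  sim <- simulate_lane(lane_config(width = 5e3, length = 1e4),
                       motility_params(radius = 1e9, d_rot = 0),
                       pathway = no_tumble_pathway,
                       n_cells = 6, duration = 20, reps = 1,
                       record = "trajectories", seed = 22)
  checked <- 0
  for (t1 in split(sim$tracks, sim$tracks$track_id)) {
    if (nrow(t1) < 300) next
    if (min(t1$y_um) <= 0 || max(t1$y_um) >= 5e3) next   # touched a wall
    d_net <- sqrt(diff(range(t1$x_um))^2 + diff(range(t1$y_um))^2)
    path_len <- sum(sqrt(diff(t1$x_um)^2 + diff(t1$y_um)^2))
    expect_equal(d_net, path_len, tolerance = 1e-6)  # straight line
    expect_equal(path_len, 20 * (nrow(t1) - 1) * 0.05, tolerance = 1e-6)
    checked <- checked + 1
  }
  expect_gte(checked, 3)
})

test_that("free-run heading decorrelates at the configured rotational diffusion", {
  sim <- simulate_lane(lane_config(width = 1e4, length = 1e5, grad_slope = 0),
                       motility_params(radius = 1e9, d_rot = 0.062),
                       pathway = no_tumble_pathway,
                       n_cells = 2, duration = 150, reps = 1,
                       record = "trajectories", seed = 23)
  t1 <- dplyr::filter(sim$tracks, track_id == sim$tracks$track_id[1])
  curve <- msod(t1)
  fit <- rotational_exponent(curve)
  expect_equal(fit$gamma_r, 1, tolerance = 0.25)
  slope <- with(curve, sum(msod * tau_s) / sum(tau_s^2))
  expect_equal(slope, 2 * 0.062, tolerance = 0.35)  # MSOD = 2 D_r tau
})

test_that("gradient-free ensembles have no drift and ~2 s wall residence", {
  sim <- sim_gradient_free()
  expect_lt(abs(sim$v_d), 2 * sim$sem)
  expect_equal(sim$v_d, sim$v_step, tolerance = 0.05)  # estimator cross-check
  epi <- episode_summary(sim)
  expect_equal(epi$mean_s[epi$kind == "wall"], 2, tolerance = 0.15)
  # detention cap: no aligned spell outlives wall_max_detention by more
  # than the discrete step granularity
  wall_spells <- sim$episodes$duration_s[sim$episodes$kind == "wall" &
                                           sim$episodes$completed]
  expect_lt(max(wall_spells), 7 + 0.2)
})

test_that("flipping chirality mirrors the lane about its axis", {
  props <- function(chir) {
    sim <- simulate_lane(lane_config(width = 10, grad_slope = 0),
                         motility_params(chirality = chir),
                         n_cells = 100, duration = 100, reps = 4,
                         record = "trajectories", seed = 31)
    region_proportions(sim$tracks, 10)$prop
  }
  p_plus <- props(1)
  p_minus <- props(-1)
  expect_lt(abs(p_plus[1] - p_minus[3]), 0.07)  # LSW <-> RSW
  expect_lt(abs(p_plus[3] - p_minus[1]), 0.07)
})

test_that("wrap-split tracks give the same drift as unwrapped bookkeeping", {
  sim <- simulate_lane(lane_config(width = 8), n_cells = 60, duration = 100,
                       reps = 3, record = "trajectories", seed = 41)
  est <- drift_velocity(sim$tracks)
  expect_equal(est$v_d, sim$v_d, tolerance = 0.1)
})

test_that("drift is positive under the gradient and maximal near w ~ 0.8 r", {
  v8 <- simulate_lane(lane_config(width = 8), n_cells = 100, duration = 150,
                      reps = 6, seed = 51)
  v25 <- simulate_lane(lane_config(width = 25), n_cells = 100, duration = 150,
                       reps = 6, seed = 52)
  expect_gt(v8$v_d, 4 * v8$sem)          # clear chemotaxis in the optimum
  expect_gt(v8$v_d, 2 * v25$v_d)         # confinement enhancement
})
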