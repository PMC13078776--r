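# Independent oracles used to freeze expected values; they deliberately do
# not share code with the implementation paths they check.

# adapted methylation by bisection on the activity equation
bisect_adapted_m <- function(c, n = 4.6, k_off = 1.7, k_on = 12, alpha = 1.7,
                             m0 = 1, a_target = 1 / 3, lo = 0, hi = 4) {
  act <- function(m) {
    1 / (1 + exp(n * (alpha * (m0 - m) + log((1 + c / k_off) / (1 + c / k_on)))))
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (act(mid) < a_target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# truncated-exponential mean on [0, pi] by numerical integration
trunc_exp_mean_numeric <- function(b) {
  stats::integrate(function(x) x * (1 / b) * exp(-x / b) / (1 - exp(-pi / b)),
                   0, pi)$value
}

# track table for a prescribed coordinate function of time
track_from_fun <- function(fx, fy, n_frames, dt = 0.05, id = "fun-1") {
  t_s <- (seq_len(n_frames) - 1) * dt
  tibble::tibble(track_id = id, frame = seq_len(n_frames) - 1L,
                 time_s = t_s, x_um = fx(t_s), y_um = fy(t_s))
}

# heading random walk (rotational diffusion) integrated into positions
brownian_heading_track <- function(d_rot, n_frames = 2000, dt = 0.05,
                                   speed = 20, seed = 1) {
  set.seed(seed)
  th <- cumsum(c(runif(1, -pi, pi), rnorm(n_frames - 1, 0, sqrt(2 * d_rot * dt))))
  x <- cumsum(c(0, speed * cos(th[-n_frames]) * dt))
  y <- cumsum(c(0, speed * sin(th[-n_frames]) * dt))
  tibble::tibble(track_id = "brown-1", frame = seq_len(n_frames) - 1L,
                 time_s = (seq_len(n_frames) - 1) * dt, x_um = x, y_um = y)
}

# gradient-free lane simulation shared by several kinematics tests
sim_gradient_free <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_lane(lane_config(width = 44, grad_slope = 0),
                              n_cells = 100, duration = 150, reps = 10,
                              record = c("episodes", "trajectories"),
                              seed = 424242)
    }
    cache
  }
})
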