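# Signaling chain: receptor activity -> methylation adaptation -> CheY-P ->
# motor CW bias -> run-to-tumble rate.

test_that("receptor activity hits its reference points", {
  p <- pathway_params()
  # both free-energy terms vanish at m = m0, c = 0
  expect_equal(receptor_activity(1, 0, p), 0.5)
  # adapted state is the fixed point a* = k_r / (k_r + k_b) = 1/3
  m_star <- adapted_state(22, p)
  expect_equal(receptor_activity(m_star, 22, p), 1 / 3, tolerance = 1e-12)
  # frozen from the bisection oracle (helper-oracles.R)
  expect_equal(bisect_adapted_m(22), 1.8486522, tolerance = 1e-6)
  expect_equal(m_star, 1.8486522, tolerance = 1e-6)
  expect_equal(adapted_state(30, p), bisect_adapted_m(30), tolerance = 1e-9)
  expect_equal(receptor_activity(1.8487, 22, p), 1 / 3, tolerance = 1e-3)
  expect_error(receptor_activity(1, -1, p), "concentration")
})

test_that("activity is monotone: decreasing in c, increasing in m", {
  p <- pathway_params()
  m_grid <- seq(0, 4, by = 0.25)
  c_grid <- c(0, 1, 5, 22, 30, 100, 1000)
  a <- outer(m_grid, c_grid, receptor_activity, params = p)
  expect_true(all(a > 0 & a < 1))
  expect_true(all(apply(a, 1, diff) < 0))  # along c
  expect_true(all(apply(a, 2, diff) > 0))  # along m
})

test_that("methylation step matches its closed-form special cases", {
  p <- pathway_params()
  # k_r (1 - a) = k_b a at a = 1/3: any m is stationary
  expect_equal(methylation_step(c(0.3, 1, 2.7), 1 / 3, 0.05, p),
               c(0.3, 1, 2.7))
  # pure methylation at rate k_r when a = 0
  expect_equal(methylation_step(1, 0, 1, p), 1.005)
  expect_error(methylation_step(1, 0.5, -0.1, p), "dt")
  expect_error(methylation_step(1, 1.2, 0.05, p), "activity")
  # clipping
  expect_equal(methylation_step(3.9999999, 0, 10, p), 4)
})

test_that("closed-loop adaptation converges monotonically to the fixed point", {
  p <- pathway_params()
  target <- 1.8486522
  for (m0 in c(0.2, 3.5)) {
    m <- m0
    path <- numeric(20000)
    for (i in seq_along(path)) {
      a <- receptor_activity(m, 22, p)
      m <- methylation_step(m, a, 0.05, p)
      path[i] <- m
    }
    expect_equal(m, target, tolerance = 5e-3)
    # monotone approach, no oscillation at dt = 0.05
    expect_true(all(diff(path) >= 0) || all(diff(path) <= 0))
  }
})

test_that("CheY-P, CW bias and switching rate reproduce the motor chain", {
  p <- pathway_params()
  expect_equal(cheyp(0, p), 0)
  expect_equal(cheyp(1, p), 7.86)
  expect_equal(cheyp(1 / 3, p), 2.62)
  expect_error(cheyp(1.1, p), "activity")

  expect_equal(cw_bias(3.1, p), 0.5)
  expect_equal(cw_bias(0, p), 0)
  b_star <- cw_bias(2.62, p)
  expect_gt(b_star, 0.145)  # the steady-state bias ~0.15
  expect_lt(b_star, 0.155)
  expect_error(cw_bias(-1, p), "CheY-P")

  expect_equal(run_to_tumble_rate(0.31, p), 1)
  expect_equal(run_to_tumble_rate(0, p), 0)
  expect_equal(run_to_tumble_rate(0.1505, p), 0.4855, tolerance = 1e-3)
  expect_error(run_to_tumble_rate(1, p), "bias")
})

test_that("steady-state chain is concentration-independent", {
  for (cc in c(5, 22, 30)) {
    ss <- pathway_steady_state(cc)
    expect_equal(ss$activity, 1 / 3, tolerance = 1e-10)
    expect_equal(ss$cheyp_um, 2.62, tolerance = 1e-9)
    expect_true(ss$cw_bias > 0.145 && ss$cw_bias < 0.155)
    expect_true(ss$switch_rate_per_s > 0.46 && ss$switch_rate_per_s < 0.51)
  }
})

test_that("a step increase in attractant suppresses activity, then readapts", {
  p <- pathway_params()
  m <- adapted_state(22, p)
  a_after_step <- receptor_activity(m, 30, p)
  expect_lt(a_after_step, 1 / 3)  # tumble suppression
  for (i in 1:40000) m <- methylation_step(m, receptor_activity(m, 30, p), 0.05, p)
  expect_equal(receptor_activity(m, 30, p), 1 / 3, tolerance = 1e-3)
})

test_that("adapted_state clips out-of-range roots with a warning", {
  p <- pathway_params(m_min = 0, m_max = 1.5)
  expect_warning(m <- adapted_state(22, p), "clip")
  expect_equal(m, 1.5)
})

test_that("parameter validation catches inconsistent constants", {
  expect_error(pathway_params(k_off = 12, k_on = 1.7), "k_off")
  expect_error(pathway_params(k_r = -1), "positive")
  expect_error(pathway_params(m_min = 4, m_max = 0), "m_min")
})
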