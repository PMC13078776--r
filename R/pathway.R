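#' Chemotaxis pathway parameters
#'
#' Constants of the coarse-grained intracellular chemotaxis model: a
#' Monod-Wyman-Changeux (MWC) receptor cluster whose activity depends on the
#' methylation level and the local attractant concentration, linear
#' methylation/demethylation adaptation, an algebraic map from activity to
#' CheY-P, a Hill function from CheY-P to motor clockwise (CW) bias, and a
#' linear map from CW bias to the run-to-tumble switching rate.
#'
#' Defaults reproduce the wild-type E. coli parameter set commonly used for
#' Tar-mediated aspartate sensing: at any fixed concentration the adapted
#' activity is `k_r / (k_r + k_b) = 1/3`, giving CheY-P 2.62 uM, CW bias
#' ~0.15 and a run-to-tumble rate of ~0.48 s^-1 (mean run ~2 s).
#'
#' @param n_cluster Receptor count per MWC cluster (dimensionless).
#' @param k_off Dissociation constant of the inactive receptor state (uM).
#' @param k_on Dissociation constant of the active receptor state (uM).
#' @param alpha Methylation free-energy coefficient (dimensionless).
#' @param m0 Reference methylation level (dimensionless).
#' @param k_r Methylation rate of CheR (s^-1).
#' @param k_b Demethylation rate of CheB (s^-1).
#' @param yp_gain CheY-P concentration per unit kinase activity (uM).
#' @param hill_k CheY-P at half-maximal CW bias (uM).
#' @param hill_n Hill coefficient of the motor response (dimensionless).
#' @param motor_rate_scale Divisor mapping CW bias to the run-to-tumble
#'   rate, `k = B / motor_rate_scale` (s).
#' @param m_min,m_max Clip bounds for the methylation level.
#'
#' @return A list of class `pathway_params`.
#' @examples
#' p <- pathway_params()
#' receptor_activity(m = 1, c = 0, p)  # 0.5 at the reference point
#' @export
pathway_params <- function(n_cluster = 4.6, k_off = 1.7, k_on = 12,
                           alpha = 1.7, m0 = 1, k_r = 0.005, k_b = 0.010,
                           yp_gain = 7.86, hill_k = 3.1, hill_n = 10.3,
                           motor_rate_scale = 0.31, m_min = 0, m_max = 4) {
  p <- list(
    n_cluster = n_cluster, k_off = k_off, k_on = k_on, alpha = alpha,
    m0 = m0, k_r = k_r, k_b = k_b, yp_gain = yp_gain, hill_k = hill_k,
    hill_n = hill_n, motor_rate_scale = motor_rate_scale,
    m_min = m_min, m_max = m_max
  )
  pos <- c("n_cluster", "k_off", "k_on", "alpha", "k_r", "k_b", "yp_gain",
           "hill_k", "hill_n", "motor_rate_scale")
  bad <- pos[!vapply(p[pos], function(v) is.numeric(v) && length(v) == 1 && v > 0, logical(1))]
  if (length(bad) > 0)
    stop_bad_input(paste0("pathway_params: fields must be positive scalars: ",
                          paste(bad, collapse = ", ")))
  if (p$k_off >= p$k_on)
    stop_bad_input("pathway_params: k_off must be smaller than k_on")
  if (p$m_min >= p$m_max)
    stop_bad_input("pathway_params: m_min must be smaller than m_max")
  structure(p, class = "pathway_params")
}

# free-energy ligand term ln((1 + c/K_off)/(1 + c/K_on)); > 0 for attractants
ligand_free_energy <- function(c, params) {
  log((1 + c / params$k_off) / (1 + c / params$k_on))
}

#' Receptor-kinase activity of the MWC cluster
#'
#' `a = 1 / (1 + exp(N * (alpha * (m0 - m) + ln((1 + c/K_off)/(1 + c/K_on)))))`.
#'
#' The methylation free energy is taken as `alpha * (m0 - m)` so that
#' activity increases with methylation (`da/dm > 0`); this is the sign under
#' which the adaptation loop `dm/dt = k_r (1 - a) - k_b a` is stable and
#' relaxes to the fixed point `a* = k_r / (k_r + k_b)`. The opposite sign,
#' which sometimes appears in displayed equations, makes methylation run
#' away; every adapted-state quantity (activity 1/3, CW bias ~0.15, switch
#' rate ~0.5 s^-1) is identical under the stable convention.
#'
#' @param m Methylation level(s), dimensionless.
#' @param c Attractant concentration(s), uM, non-negative.
#' @param params A [pathway_params()] object.
#' @return Activity in (0, 1), vectorized over `m` and `c`.
#' @export
receptor_activity <- function(m, c, params = pathway_params()) {
  if (any(c < 0)) stop_bad_input("receptor_activity: concentration must be >= 0")
  f <- params$n_cluster * (params$alpha * (params$m0 - m) + ligand_free_energy(c, params))
  1 / (1 + exp(f))
}

#' One explicit-Euler methylation update
#'
#' `m <- clip(m + (k_r (1 - a) - k_b a) dt, m_min, m_max)`. Adaptation
#' timescales (minutes) are far slower than the simulation step (0.05 s), so
#' no sub-stepping is used.
#'
#' @param m Methylation level(s).
#' @param a Receptor activity in (0, 1).
#' @param dt Time step (s), positive.
#' @inheritParams receptor_activity
#' @return Updated methylation level(s), clipped to `[m_min, m_max]`.
#' @export
methylation_step <- function(m, a, dt, params = pathway_params()) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop_bad_input("methylation_step: dt must be a positive scalar")
  if (any(a < 0) || any(a > 1))
    stop_bad_input("methylation_step: activity must lie in [0, 1]")
  m_new <- m + (params$k_r * (1 - a) - params$k_b * a) * dt
  pmin(pmax(m_new, params$m_min), params$m_max)
}

#' CheY-P concentration from kinase activity
#'
#' @param a Activity in \[0, 1\].
#' @inheritParams receptor_activity
#' @return CheY-P concentration (uM), `yp_gain * a`.
#' @export
cheyp <- function(a, params = pathway_params()) {
  if (any(a < 0) || any(a > 1))
    stop_bad_input("cheyp: activity must lie in [0, 1]")
  params$yp_gain * a
}

#' Motor clockwise bias from CheY-P
#'
#' Hill response `B = Yp^n / (Yp^n + K^n)` with default half-point 3.1 uM
#' and coefficient 10.3, the steep ultrasensitive motor switch.
#'
#' @param yp CheY-P concentration (uM), non-negative.
#' @inheritParams receptor_activity
#' @return CW bias in \[0, 1).
#' @export
cw_bias <- function(yp, params = pathway_params()) {
  if (any(yp < 0)) stop_bad_input("cw_bias: CheY-P must be >= 0")
  # computed on the ratio scale to avoid overflow of yp^10.3 at large yp
  ratio <- (yp / params$hill_k)^params$hill_n
  ratio / (1 + ratio)
}

#' Run-to-tumble switching rate from CW bias
#'
#' The CCW-to-CW motor switching rate grows linearly with bias:
#' `k = B / motor_rate_scale`.
#'
#' @param bias CW bias in \[0, 1).
#' @inheritParams receptor_activity
#' @return Switching rate (s^-1).
#' @export
run_to_tumble_rate <- function(bias, params = pathway_params()) {
  if (any(bias < 0) || any(bias >= 1))
    stop_bad_input("run_to_tumble_rate: bias must lie in [0, 1)")
  bias / params$motor_rate_scale
}

#' Adapted methylation level at a fixed concentration
#'
#' Solves `receptor_activity(m*, c) = k_r / (k_r + k_b)` for `m*`. The
#' logistic activity is analytically invertible in `m`, so the fixed point
#' is computed in closed form:
#' `m* = m0 + (L(c) - ln(1/a* - 1)/N) / alpha` with
#' `L(c) = ln((1 + c/K_off)/(1 + c/K_on))`. The result is clipped to
#' `[m_min, m_max]` with a warning when the unconstrained root lies outside.
#'
#' Used to initialize simulated cells in equilibrium with their local
#' concentration, so no burn-in transient is needed.
#'
#' @param c Concentration(s), uM.
#' @inheritParams receptor_activity
#' @return Adapted methylation level(s) `m*`.
#' @examples
#' adapted_state(22)                      # ~1.8487
#' receptor_activity(adapted_state(22), 22)  # 1/3
#' @export
adapted_state <- function(c, params = pathway_params()) {
  if (any(c < 0)) stop_bad_input("adapted_state: concentration must be >= 0")
  a_star <- params$k_r / (params$k_r + params$k_b)
  m_star <- params$m0 +
    (ligand_free_energy(c, params) - log(1 / a_star - 1) / params$n_cluster) /
    params$alpha
  out_of_range <- m_star < params$m_min | m_star > params$m_max
  if (any(out_of_range))
    warning("adapted_state: fixed point outside [m_min, m_max]; returning clipped bound")
  pmin(pmax(m_star, params$m_min), params$m_max)
}

#' Steady-state pathway chain at a fixed concentration
#'
#' Convenience summary of the gradient-free operating point: adapted
#' methylation, activity, CheY-P, CW bias, run-to-tumble rate, and the mean
#' run duration implied by the rate.
#'
#' @inheritParams adapted_state
#' @return A tibble with one row per concentration.
#' @export
pathway_steady_state <- function(c = 22, params = pathway_params()) {
  m_star <- adapted_state(c, params)
  a <- receptor_activity(m_star, c, params)
  yp <- cheyp(a, params)
  b <- cw_bias(yp, params)
  k <- run_to_tumble_rate(b, params)
  tibble(
    concentration_um = c, m_star = m_star, activity = a, cheyp_um = yp,
    cw_bias = b, switch_rate_per_s = k, mean_run_s = 1 / k
  )
}
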