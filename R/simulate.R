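# Agent-based run-and-tumble simulation inside a lane.
#
# All cells of all repeats evolve in one vectorized state (cells are
# independent, so repeats can share the step loop); a 150 s / 100 cell /
# 50 repeat protocol runs in seconds. Wall codes: 0 = free, 1 = bottom wall
# (y = 0, the LSW), 2 = top wall (y = width, the RSW).

#' Motility parameters of a surface-swimming cell
#'
#' @param speed Run speed v0 (um/s).
#' @param radius Radius of circular surface swimming (um). The bottom
#'   surface imposes a constant angular velocity `chirality * speed/radius`
#'   on the heading during runs.
#' @param d_rot Rotational diffusion coefficient (rad^2/s).
#' @param dt Time step (s).
#' @param tumble_exit_rate Tumble-to-run switching rate (s^-1); at 5 s^-1
#'   the mean tumble lasts 0.2 s.
#' @param wall_max_detention Maximum time (s) a cell may swim aligned with a
#'   sidewall before a tumble is forced. The default 7 s, combined with the
#'   gradient-free switching rate ~0.485 s^-1, calibrates the mean wall
#'   residence to ~2 s.
#' @param chirality +1 or -1. With the default +1 the heading angle
#'   increases during runs (counterclockwise in standard mathematical
#'   coordinates, i.e. the clockwise circling seen when imaging cells from
#'   above), so up-gradient swimmers accumulate on the y = width sidewall
#'   (the RSW) and chemotactic drift is positive. Flipping the sign mirrors
#'   the lane about its axis.
#' @return A list of class `motility_params`.
#' @export
motility_params <- function(speed = 20, radius = 10, d_rot = 0.062,
                            dt = 0.05, tumble_exit_rate = 5,
                            wall_max_detention = 7, chirality = 1) {
  if (speed <= 0 || radius <= 0 || dt <= 0 || tumble_exit_rate <= 0)
    stop_bad_input("motility_params: speed, radius, dt, tumble_exit_rate must be positive")
  if (d_rot < 0) stop_bad_input("motility_params: d_rot must be >= 0")
  if (wall_max_detention <= 0)
    stop_bad_input("motility_params: wall_max_detention must be positive")
  if (!chirality %in% c(-1, 1))
    stop_bad_input("motility_params: chirality must be +1 or -1")
  structure(list(speed = speed, radius = radius, d_rot = d_rot, dt = dt,
                 tumble_exit_rate = tumble_exit_rate,
                 wall_max_detention = wall_max_detention,
                 chirality = chirality),
            class = "motility_params")
}

#' Lane geometry and attractant gradient
#'
#' A rectangular lane `[0, length] x [0, width]` with a linear attractant
#' profile `c(x) = grad_slope * x + c_intercept` (x clipped to the lane).
#'
#' @param width Lane width w (um).
#' @param length Lane length along the gradient (um).
#' @param grad_slope Gradient dc/dx (uM/um); 0 gives the no-gradient control.
#' @param c_intercept Concentration at x = 0 (uM).
#' @return A list of class `lane_config`.
#' @export
lane_config <- function(width, length = 160, grad_slope = 0.05,
                        c_intercept = 22) {
  if (width <= 0 || length <= 0)
    stop_bad_input("lane_config: width and length must be positive")
  if (c_intercept < 0 || c_intercept + grad_slope * length < 0)
    stop_bad_input("lane_config: concentration must be non-negative across the lane")
  structure(list(width = width, length = length, grad_slope = grad_slope,
                 c_intercept = c_intercept),
            class = "lane_config")
}

#' Attractant concentration at a position
#'
#' @param x Position(s) along the lane (um); values outside the lane are
#'   clipped, so transiently out-of-bounds positions are safe.
#' @param lane A [lane_config()].
#' @return Concentration(s) in uM.
#' @export
concentration_at <- function(x, lane) {
  lane$grad_slope * pmin(pmax(x, 0), lane$length) + lane$c_intercept
}

#' Sidewall collision rule
#'
#' A run step that would carry a cell beyond a sidewall instead clamps it to
#' the wall and aligns the heading with the wall, preserving the sign of the
#' incoming x-velocity (`cos(theta) >= 0` maps to heading 0, otherwise pi;
#' an exactly perpendicular hit breaks the tie toward +x).
#'
#' @param y Proposed y position(s) (um).
#' @param theta Heading(s) (rad).
#' @param width Lane width (um).
#' @return A list with clamped `y`, aligned `theta`, and integer `on_wall`
#'   (0 none, 1 bottom wall y = 0, 2 top wall y = width).
#' @export
wall_collision <- function(y, theta, width) {
  on_wall <- integer(length(y))
  hit_top <- y > width
  hit_bot <- y < 0
  hit <- hit_top | hit_bot
  y[hit_top] <- width
  y[hit_bot] <- 0
  theta[hit] <- ifelse(cos(theta[hit]) >= 0, 0, pi)
  on_wall[hit_top] <- 2L
  on_wall[hit_bot] <- 1L
  list(y = y, theta = theta, on_wall = on_wall)
}

#' Periodic x-boundary with y randomization
#'
#' Cells leaving through either x end reappear at the other with a fresh
#' uniform y position; heading and pathway state are preserved, wall
#' attachment is cleared. Uses the current RNG stream for the redraw.
#'
#' @param x Position(s) (um).
#' @param lane A [lane_config()].
#' @return `x` wrapped into `[0, length)`.
#' @export
wrap_x <- function(x, lane) {
  x %% lane$length
}

#' Simulate run-and-tumble chemotaxis in a lane
#'
#' Cells start uniformly placed with uniform headings and their pathway
#' adapted to the local concentration, then alternate runs and tumbles:
#'
#' * running cells sense `c(x)`, update methylation by one Euler step, and
#'   switch to a tumble with probability `k dt` where
#'   `k = cw_bias(cheyp(activity)) / motor_rate_scale`; wall-attached cells
#'   whose detention clock exceeds `wall_max_detention` tumble forcibly;
#' * free runners turn at the constant chiral rate `speed/radius` plus
#'   rotational diffusion and translate at `speed`; wall-attached runners
#'   translate along the wall with frozen heading (no curvature, no
#'   diffusion while aligned);
#' * tumbling cells do not translate and exit at `tumble_exit_rate`; at exit
#'   a signed tumble angle is drawn from the sidewall model (`b_sidewall`)
#'   when the cell lies within `tumble_region_d` of either wall (the
#'   sidewall band of the region classification, which includes all
#'   wall-attached cells), else from the middle-area model (`b_middle`).
#'   For a wall-attached cell, a post-tumble heading pointing into the wall
#'   re-aligns it (detention clock reset); otherwise it detaches;
#' * sidewall collisions align cells with the wall; cells crossing an x end
#'   are recycled with a random y.
#'
#' @param lane A [lane_config()].
#' @param motility A [motility_params()].
#' @param pathway A [pathway_params()].
#' @param n_cells Cells per repeat.
#' @param duration Simulated time per repeat (s).
#' @param reps Independent repeats (cells do not interact, so all repeats
#'   share one vectorized loop).
#' @param b_sidewall,b_middle Characteristic tumble angles (rad) of the
#'   sidewall and middle-area truncated-exponential models.
#' @param tumble_region_d Half-width (um) of the sidewall bands within
#'   which tumble angles use the sidewall model; matches the 3 um region
#'   threshold of the trajectory classification. In lanes narrower than
#'   `2 * tumble_region_d` every tumble is a small sidewall reorientation,
#'   which suppresses direction conversion and with it chemotactic drift -
#'   one of the two ingredients of the optimal-width peak.
#' @param record Character vector; any of `"episodes"` (run/tumble/wall
#'   episode durations) and `"trajectories"` (full tracks, split at
#'   x-boundary recycling). Drift is always computed.
#' @param burn_in Initial time (s) excluded from the drift estimate. Cells
#'   start pathway-adapted, so the default is 0.
#' @param seed Optional integer seed for full reproducibility.
#'
#' @return An object of class `lane_sim`: a list with per-repeat drift
#'   estimates (`$drift`, lag-regression slope per repeat), the ensemble
#'   mean `$v_d` and `$sem`, the per-step displacement cross-check
#'   `$v_step`, pooled lag means `$lag_means`, optionally `$episodes` and
#'   `$tracks` tibbles, and `$config`.
#' @examples
#' sim <- simulate_lane(lane_config(width = 8), n_cells = 20, duration = 30,
#'                      reps = 2, seed = 1)
#' glance(sim)
#' @export
simulate_lane <- function(lane, motility = motility_params(),
                          pathway = pathway_params(), n_cells = 100,
                          duration = 150, reps = 50,
                          b_sidewall = 0.25, b_middle = 1.35,
                          tumble_region_d = 3, record = NULL, burn_in = 0,
                          seed = NULL) {
  stopifnot(inherits(lane, "lane_config"), inherits(motility, "motility_params"),
            inherits(pathway, "pathway_params"))
  dt <- motility$dt
  if (duration <= dt) stop_bad_input("simulate_lane: duration must exceed dt")
  if (n_cells < 1 || reps < 1) stop_bad_input("simulate_lane: need n_cells, reps >= 1")
  record <- match.arg(record, c("episodes", "trajectories"), several.ok = TRUE)
  rec_epi <- "episodes" %in% record
  rec_trk <- "trajectories" %in% record
  if (!is.null(seed)) set.seed(seed)

  # local copies: the step loop avoids per-call validation overhead
  v0 <- motility$speed; r <- motility$radius; Dr <- motility$d_rot
  om <- motility$chirality * v0 / r
  sig <- sqrt(2 * Dr * dt)
  pexit <- motility$tumble_exit_rate * dt
  Tmax <- motility$wall_max_detention
  w <- lane$width; len <- lane$length
  grad <- lane$grad_slope; c0 <- lane$c_intercept
  N <- pathway$n_cluster; al <- pathway$alpha; m0v <- pathway$m0
  koff <- pathway$k_off; kon <- pathway$k_on
  kR <- pathway$k_r; kB <- pathway$k_b
  mmin <- pathway$m_min; mmax <- pathway$m_max
  ypg <- pathway$yp_gain; hk <- pathway$hill_k; hn <- pathway$hill_n
  mrs <- pathway$motor_rate_scale
  bsw <- b_sidewall; bma <- b_middle
  csw <- 1 - exp(-pi / bsw); cma <- 1 - exp(-pi / bma)  # truncation constants

  steps <- round(duration / dt)
  n <- n_cells * reps
  repid <- rep(seq_len(reps), each = n_cells)

  x <- runif(n, 0, len)
  y <- runif(n, 0, w)
  th <- runif(n, -pi, pi)
  m <- adapted_state(grad * x + c0, pathway)
  tumbling <- logical(n)
  onwall <- integer(n)
  wclock <- numeric(n)
  xu <- x  # unwrapped x: accumulates true displacement across recycling

  # drift bookkeeping: the lag-n mean displacement of a track telescopes to
  # (sum of last n frames - sum of first n frames) / (frames - n), so only
  # the first and last 39 frames of unwrapped x are needed per agent
  nlag <- 39L
  b0 <- round(burn_in / dt)
  n_frames <- steps + 1L - b0
  if (n_frames <= 2L * nlag)
    stop_bad_input("simulate_lane: duration too short for the lag-39 drift estimator")
  Xfirst <- matrix(NA_real_, n, nlag)
  Xbuf <- matrix(NA_real_, n, nlag)  # circular buffer of the trailing frames
  xu_at_b0 <- NULL
  store_frame <- function(fi, vals) {
    if (fi < nlag) Xfirst[, fi + 1L] <<- vals
    Xbuf[, (fi %% nlag) + 1L] <<- vals
  }
  if (b0 == 0L) { store_frame(0L, xu); xu_at_b0 <- xu }

  codes <- if (rec_epi) matrix(0L, steps + 1L, n) else NULL
  XR <- if (rec_trk) matrix(NA_real_, steps + 1L, n) else NULL
  YR <- if (rec_trk) matrix(NA_real_, steps + 1L, n) else NULL
  if (rec_trk) { XR[1L, ] <- x; YR[1L, ] <- y }

  for (s in seq_len(steps)) {
    run0 <- !tumbling

    ## sense, adapt, run-to-tumble switching
    ridx <- which(run0)
    if (length(ridx) > 0) {
      cc <- grad * pmin(pmax(x[ridx], 0), len) + c0
      f <- N * (al * (m0v - m[ridx]) + log((1 + cc / koff) / (1 + cc / kon)))
      a <- 1 / (1 + exp(f))
      m[ridx] <- pmin(pmax(m[ridx] + (kR * (1 - a) - kB * a) * dt, mmin), mmax)
      ratio <- (ypg * a / hk)^hn
      krate <- (ratio / (1 + ratio)) / mrs
      sw <- runif(length(ridx)) < krate * dt
      forced <- onwall[ridx] > 0L & wclock[ridx] > Tmax
      newt <- ridx[sw | forced]
      if (length(newt) > 0) tumbling[newt] <- TRUE
    }

    ## tumble exits (cells already tumbling at step start; exiters move
    ## this same step, so tumble durations are geometric with mean 1/rate)
    tidx <- which(!run0)
    if (length(tidx) > 0) {
      ex <- runif(length(tidx)) < pexit
      eidx <- tidx[ex]
      if (length(eidx) > 0) {
        # angle model by area (sidewall bands vs middle), as in the region
        # classification; wall-attached cells are always in a band
        onw <- y[eidx] <= tumble_region_d | y[eidx] >= w - tumble_region_d
        mag <- numeric(length(eidx))
        u <- runif(length(eidx))
        mag[onw] <- -bsw * log(1 - u[onw] * csw)
        mag[!onw] <- -bma * log(1 - u[!onw] * cma)
        sgn <- ifelse(runif(length(eidx)) < 0.5, -1, 1)
        thn <- wrap_angle(th[eidx] + sgn * mag)
        top <- onwall[eidx] == 2L
        bot <- onwall[eidx] == 1L
        stay <- (top & sin(thn) > 0) | (bot & sin(thn) < 0)
        th[eidx] <- ifelse(stay, ifelse(cos(thn) >= 0, 0, pi), thn)
        onwall[eidx[!stay]] <- 0L
        wclock[eidx] <- 0
        tumbling[eidx] <- FALSE
      }
    }

    ## movement: all currently-running cells (tumble entrants sit still)
    mv <- which(!tumbling)
    if (length(mv) > 0) {
      free <- mv[onwall[mv] == 0L]
      wall <- mv[onwall[mv] > 0L]
      if (length(free) > 0)
        th[free] <- wrap_angle(th[free] + om * dt + rnorm(length(free), 0, sig))
      dx <- numeric(n); dy <- numeric(n)
      dx[mv] <- v0 * cos(th[mv]) * dt
      if (length(free) > 0) dy[free] <- v0 * sin(th[free]) * dt
      if (length(wall) > 0) wclock[wall] <- wclock[wall] + dt
      xn <- x + dx
      yn <- y + dy
      hit_top <- which(yn > w)
      if (length(hit_top) > 0) {
        yn[hit_top] <- w
        th[hit_top] <- ifelse(cos(th[hit_top]) >= 0, 0, pi)
        onwall[hit_top] <- 2L
        wclock[hit_top] <- 0
      }
      hit_bot <- which(yn < 0)
      if (length(hit_bot) > 0) {
        yn[hit_bot] <- 0
        th[hit_bot] <- ifelse(cos(th[hit_bot]) >= 0, 0, pi)
        onwall[hit_bot] <- 1L
        wclock[hit_bot] <- 0
      }
      iw <- which(xn < 0 | xn > len)
      if (length(iw) > 0) {
        # recycling emulates a periodic window of an infinite ramp: shift
        # methylation by dL/alpha so the cluster free energy (hence the
        # activity and tumble rate) is continuous across the wrap, instead
        # of letting the 8 uM concentration jump act like a ligand step
        c_old <- grad * pmin(pmax(xn[iw], 0), len) + c0
        xn[iw] <- xn[iw] %% len
        c_new <- grad * pmin(pmax(xn[iw], 0), len) + c0
        dL <- log((1 + c_new / koff) / (1 + c_new / kon)) -
          log((1 + c_old / koff) / (1 + c_old / kon))
        m[iw] <- pmin(pmax(m[iw] + dL / al, mmin), mmax)
        yn[iw] <- runif(length(iw), 0, w)
        onwall[iw] <- 0L
        wclock[iw] <- 0
      }
      xu <- xu + dx
      x <- xn
      y <- yn
    }

    fi <- s - b0
    if (fi == 0L) xu_at_b0 <- xu
    if (fi >= 0L) store_frame(fi, xu)
    if (rec_epi) codes[s + 1L, ] <- tumbling * 2L + (onwall > 0L)
    if (rec_trk) { XR[s + 1L, ] <- x; YR[s + 1L, ] <- y }
  }

  ## lag-regression drift per repeat
  lags <- seq(1L, nlag, by = 2L)
  SF <- t(apply(Xfirst, 1L, cumsum))                       # n x 39
  last_cols <- ((n_frames - nlag):(n_frames - 1L)) %% nlag + 1L
  Xlast <- Xbuf[, last_cols, drop = FALSE]                 # oldest..newest
  SL <- t(apply(Xlast[, nlag:1L, drop = FALSE], 1L, cumsum))  # SL[, k] = sum of last k
  md <- vapply(lags, function(k) {
    per_agent <- (SL[, k] - SF[, k]) / (n_frames - k)
    as.vector(rowsum(per_agent, repid)) / n_cells
  }, numeric(reps))                                        # reps x length(lags)
  md <- matrix(md, nrow = reps)
  X <- cbind(1, lags * dt)
  beta <- solve(crossprod(X), crossprod(X, t(md)))         # 2 x reps
  drift <- tibble(rep = seq_len(reps), v_d = beta[2L, ], intercept = beta[1L, ])
  lag_means <- tibble(lag = lags, tau_s = lags * dt, mean_dx = colMeans(md))
  v_step <- mean(xu - xu_at_b0) / ((n_frames - 1L) * dt)

  out <- list(
    drift = drift,
    v_d = mean(drift$v_d),
    sem = stats::sd(drift$v_d) / sqrt(reps),
    v_step = v_step,
    lag_means = lag_means,
    episodes = if (rec_epi) collect_episodes(codes, repid, dt) else NULL,
    tracks = if (rec_trk) assemble_tracks(XR, YR, repid, dt, len) else NULL,
    config = list(lane = lane, motility = motility, pathway = pathway,
                  n_cells = n_cells, duration = duration, reps = reps,
                  b_sidewall = b_sidewall, b_middle = b_middle,
                  tumble_region_d = tumble_region_d,
                  burn_in = burn_in, seed = seed)
  )
  structure(out, class = "lane_sim")
}

# Episode spells from the per-frame state code (0 run-free, 1 run-wall,
# 2 tumble-free, 3 tumble-wall):
#  * run: code-0 spans; completed when a tumble follows (next code 2),
#    censored when a wall collision or the simulation end cuts them short;
#  * tumble: code-2/3 spans; completed unless the simulation ends in them;
#  * wall: code-1 spans of wall-aligned swimming; completed when a tumble
#    starts at the wall (next code 3, spontaneous or detention-forced),
#    censored by x-recycling (next code 0) or the simulation end.
# Censored spells are returned flagged so means can be exposure-corrected.
collect_episodes <- function(codes, repid, dt) {
  n <- ncol(codes)
  acc <- vector("list", n)
  for (j in seq_len(n)) {
    rl <- rle(codes[, j])
    v <- rl$values
    l <- rl$lengths
    nxt <- c(v[-1L], NA_integer_)
    is_run <- v == 0L
    is_wall <- v == 1L
    is_tum <- v >= 2L
    acc[[j]] <- tibble(
      kind = c(rep("run", sum(is_run)), rep("wall", sum(is_wall)),
               rep("tumble", sum(is_tum))),
      rep = repid[j],
      duration_s = c(l[is_run], l[is_wall], l[is_tum]) * dt,
      completed = c(!is.na(nxt[is_run]) & nxt[is_run] == 2L,
                    !is.na(nxt[is_wall]) & nxt[is_wall] == 3L,
                    !is.na(nxt[is_tum]))
    )
  }
  dplyr::bind_rows(acc)
}

# Split recorded positions into tracks at x-recycling jumps (a per-step run
# displacement is at most v0*dt << length/2, so a jump identifies a wrap).
assemble_tracks <- function(XR, YR, repid, dt, len) {
  n_frames <- nrow(XR)
  n <- ncol(XR)
  jump <- rbind(FALSE, abs(diff(XR)) > len / 2)
  seg <- apply(jump, 2L, cumsum)
  agent <- rep(seq_len(n), each = n_frames)
  tibble(
    track_id = paste0("sim", agent, ".", as.vector(seg) + 1L),
    rep = rep(repid, each = n_frames),
    frame = rep(seq_len(n_frames) - 1L, times = n),
    time_s = rep((seq_len(n_frames) - 1L) * dt, times = n),
    x_um = as.vector(XR),
    y_um = as.vector(YR)
  )
}

#' Summarize recorded episode durations
#'
#' Episode spells are right-censored by wall collisions, x-boundary
#' recycling, and the end of the simulation, so `mean_s` is the
#' exposure-corrected mean (total time in the state divided by the number
#' of completed spells) - the maximum-likelihood mean for exponential-like
#' episodes under independent censoring, and the quantity the
#' detention-time calibration `(1 - exp(-k T)) / k` refers to for wall
#' residence. The naive average over completed spells only
#' (`mean_completed_s`) is biased short and reported for reference.
#'
#' @param sim A `lane_sim` with `record = "episodes"`.
#' @return A tibble with one row per episode kind (run, tumble, wall).
#' @export
episode_summary <- function(sim) {
  stopifnot(inherits(sim, "lane_sim"))
  if (is.null(sim$episodes))
    stop_bad_input("episode_summary: simulate with record = 'episodes'")
  sim$episodes |>
    dplyr::group_by(.data$kind) |>
    dplyr::summarise(n_completed = sum(.data$completed),
                     n_censored = sum(!.data$completed),
                     mean_s = sum(.data$duration_s) / sum(.data$completed),
                     mean_completed_s = mean(.data$duration_s[.data$completed]),
                     .groups = "drop")
}

#' @export
print.lane_sim <- function(x, ...) {
  cfg <- x$config
  cat("Lane chemotaxis simulation\n")
  cat(sprintf("  lane %g x %g um, gradient %g uM/um, r = %g um\n",
              cfg$lane$length, cfg$lane$width, cfg$lane$grad_slope,
              cfg$motility$radius))
  cat(sprintf("  %d cells x %g s x %d repeats (dt = %g s)\n",
              cfg$n_cells, cfg$duration, cfg$reps, cfg$motility$dt))
  cat(sprintf("  drift v_d = %.3f +/- %.3f um/s (lag regression; per-step check %.3f)\n",
              x$v_d, x$sem, x$v_step))
  invisible(x)
}

#' @export
glance.lane_sim <- function(x, ...) {
  epi <- if (!is.null(x$episodes)) episode_summary(x) else NULL
  pick <- function(k) if (is.null(epi) || !k %in% epi$kind) NA_real_ else epi$mean_s[epi$kind == k]
  tibble(
    width_um = x$config$lane$width,
    radius_um = x$config$motility$radius,
    grad_slope = x$config$lane$grad_slope,
    n_cells = x$config$n_cells,
    reps = x$config$reps,
    duration_s = x$config$duration,
    v_d = x$v_d,
    sem = x$sem,
    v_step = x$v_step,
    mean_run_s = pick("run"),
    mean_tumble_s = pick("tumble"),
    mean_wall_s = pick("wall")
  )
}
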