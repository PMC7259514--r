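#' Simulation configuration for fold-transition trajectories
#'
#' Bundles the parameters of the stochastic saddle-node (fold) normal form
#' \deqn{\dot x = y + a x^2 - x^3 + \gamma \xi(t), \qquad \dot y = \epsilon,}
#' integrated as a discrete map at the readout interval `dt`: the
#' deterministic drift enters Euler-style as `dt * f(x, y)` and the noise is
#' added per readout as `gamma * xi_k` with `xi_k` a zero-mean unit-variance
#' deviate. When `cubic = FALSE` the `-x^3` saturation term is dropped and
#' the model reduces to the minimal fold normal form `y + a x^2`.
#'
#' @param a Quadratic coefficient; for the cubic model it sets the
#'   post-transition steady-state position (the positive root of
#'   `a x^2 - x^3 = 0` as the slow variable approaches zero from above).
#' @param gamma Noise amplitude (standard deviation of the per-readout kick).
#' @param epsilon Drift rate of the slow variable `y`, per second.
#' @param dt Readout interval in seconds.
#' @param duration Total simulated time in seconds.
#' @param tstar_range Length-2 numeric, the (min, max) of the uniform
#'   distribution the transition time `t*` is drawn from, in seconds.
#' @param noise_kind `"gaussian"` or `"uniform"`; both are scaled to unit
#'   variance so `gamma` always means the per-step noise standard deviation.
#' @param cubic Logical, include the `-x^3` saturation term.
#' @param x_bound Overflow guard: once `|x|` exceeds this bound the
#'   trajectory is clipped there and the escape time recorded. Default
#'   `10 * a`.
#' @param seed Optional integer seed recorded in the configuration and used
#'   by the simulators for reproducibility.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(a = 4, gamma = 0.063, epsilon = 100, dt = 0.010,
                       duration = 1.5, tstar_range = c(0.350, 0.700),
                       noise_kind = c("gaussian", "uniform"), cubic = TRUE,
                       x_bound = NULL, seed = NULL) {
  noise_kind <- match.arg(noise_kind)
  if (is.null(x_bound)) x_bound <- 10 * max(abs(a), 1)
  cfg <- list(a = a, gamma = gamma, epsilon = epsilon, dt = dt,
              duration = duration, tstar_range = as.numeric(tstar_range),
              noise_kind = noise_kind, cubic = isTRUE(cubic),
              x_bound = x_bound, seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    "dt must be > 0" = is.numeric(cfg$dt) && cfg$dt > 0,
    "gamma must be >= 0" = is.numeric(cfg$gamma) && cfg$gamma >= 0,
    "epsilon must be >= 0" = is.numeric(cfg$epsilon) && cfg$epsilon >= 0,
    "duration must be positive" = cfg$duration > 0,
    "tstar_range must be length 2" = length(cfg$tstar_range) == 2,
    "tstar_range must be ordered" =
      cfg$tstar_range[1] <= cfg$tstar_range[2],
    "duration must cover tstar_range" =
      cfg$duration >= cfg$tstar_range[2],
    "x_bound must be positive" = cfg$x_bound > 0
  )
  invisible(cfg)
}

#' Construct a trajectory object
#'
#' Container for a simulated 1-D trajectory: sample times, the fast variable
#' `x` (the dot position / velocity analogue), optionally the latent slow
#' variable `y`, the true transition time, the randomized direction and the
#' model kind.
#'
#' @param t Time vector (seconds, uniformly spaced).
#' @param x Fast-variable vector, same length as `t`.
#' @param y Optional slow-variable vector.
#' @param tstar_true Transition time in seconds (where `y` crosses zero, or
#'   the step time for Heaviside controls).
#' @param direction +1 or -1, the randomized sign applied to `x`.
#' @param kind `"fold"` or `"heaviside"`.
#' @param cfg The `sim_config` used (stored for provenance).
#' @param seed Integer seed actually used for this trajectory.
#' @param escape_time Time at which `|x|` hit the overflow bound, or `NA`.
#' @param detrended Logical, whether `x` has been detrended.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(t, x, y = NULL, tstar_true, direction = 1L,
                       kind = c("fold", "heaviside"), cfg = NULL,
                       seed = NULL, escape_time = NA_real_,
                       detrended = FALSE) {
  kind <- match.arg(kind)
  stopifnot(
    "t and x must have equal length" = length(t) == length(x),
    "t must be strictly increasing" = all(diff(t) > 0),
    "direction must be +1 or -1" = direction %in% c(-1, 1),
    "tstar_true must lie within the time span" =
      tstar_true >= t[1] && tstar_true <= t[length(t)]
  )
  if (!is.null(y)) stopifnot(length(y) == length(x))
  structure(list(t = t, x = x, y = y, tstar_true = tstar_true,
                 direction = as.integer(direction), kind = kind, cfg = cfg,
                 seed = seed, escape_time = escape_time,
                 detrended = isTRUE(detrended)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %s, %d samples @ dt=%gs, t*=%.3fs, dir=%+d%s>\n",
              x$kind, length(x$t), diff(x$t[1:2]), x$tstar_true,
              x$direction, if (x$detrended) ", detrended" else ""))
  invisible(x)
}

# Stable quasi-static branch of y + a x^2 (- x^3): the fixed point the system
# relaxes to before the transition. For the cubic model the pre-transition
# branch is the smallest real root (the one continuing x ~ -sqrt(-y/a) as
# y -> 0-); it has negative linearization hence is stable. Vectorized over y;
# returns 0 for y >= 0 (the branch terminates at the fold point).
stable_branch <- function(y, a, cubic = TRUE) {
  vapply(y, function(yi) {
    if (yi >= 0) return(0)
    if (!cubic) return(-sqrt(-yi / a))
    r <- polyroot(c(yi, 0, a, -1))
    re <- Re(r[abs(Im(r)) < 1e-8 * (1 + abs(r))])
    if (length(re) == 0) return(-sqrt(-yi / a))
    min(re)
  }, numeric(1))
}

# Per-step noise deviates with unit variance.
noise_deviates <- function(n, kind) {
  switch(kind,
         gaussian = stats::rnorm(n),
         uniform = stats::runif(n, -sqrt(3), sqrt(3)))
}

#' Integrate the fold map from a given initial slow value
#'
#' Core integrator shared by the minimal and cubic fold simulators. The
#' update per readout step is
#' `x <- x + dt * (y + a*x^2 - cubic*x^3) + gamma * xi` and
#' `y <- y + dt * epsilon`. Once `|x|` exceeds `cfg$x_bound` the trajectory
#' is clipped at the bound (holding its sign) and the escape time recorded.
#'
#' @param cfg A [sim_config()].
#' @param y0 Initial slow value.
#' @param x0 Initial fast value; defaults to the stable quasi-static branch
#'   at `y0` when `y0 < 0`, else 0.
#' @param seed Optional seed overriding `cfg$seed`.
#' @return A [trajectory()] with the latent `y` stored and `tstar_true` set
#'   to the time `y` first reaches zero (clamped to the trial span).
#' @export
simulate_fold <- function(cfg, y0, x0 = NULL, seed = cfg$seed) {
  validate_sim_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x0)) {
    x0 <- if (y0 < 0) stable_branch(y0, cfg$a, cfg$cubic) else 0
  }
  n <- floor(cfg$duration / cfg$dt) + 1L
  tt <- (seq_len(n) - 1L) * cfg$dt
  x <- numeric(n); y <- numeric(n)
  x[1] <- x0; y[1] <- y0
  xi <- if (cfg$gamma > 0) cfg$gamma * noise_deviates(n - 1L, cfg$noise_kind)
        else numeric(n - 1L)
  escape <- NA_real_
  for (k in seq_len(n - 1L)) {
    drift <- y[k] + cfg$a * x[k]^2 - if (cfg$cubic) x[k]^3 else 0
    xn <- x[k] + cfg$dt * drift + xi[k]
    if (!is.na(escape) || abs(xn) >= cfg$x_bound) {
      if (is.na(escape)) escape <- tt[k + 1L]
      xn <- sign(xn) * cfg$x_bound
      x[(k + 1L):n] <- xn
      y[(k + 1L):n] <- y[k] + cfg$dt * cfg$epsilon * seq_len(n - k)
      break
    }
    x[k + 1L] <- xn
    y[k + 1L] <- y[k] + cfg$dt * cfg$epsilon
  }
  tstar <- if (y0 >= 0) tt[1] else if (cfg$epsilon > 0) -y0 / cfg$epsilon
           else Inf
  tstar <- min(max(tstar, tt[1]), tt[n])
  trajectory(tt, x, y, tstar_true = tstar, direction = 1L, kind = "fold",
             cfg = cfg, seed = seed, escape_time = escape)
}

#' Simulate the minimal fold normal form
#'
#' Integrates `x' = y + a*x^2 + noise`, `y' = epsilon` (no cubic saturation),
#' starting from the stable root of `y0 + a x^2` when `y0 < 0`. This is the
#' minimal model of a saddle-node transition: for `y < 0` a stable/unstable
#' fixed-point pair exists, the pair annihilates at `y = 0`, and for `y > 0`
#' only runaway growth remains.
#'
#' @inheritParams simulate_fold
#' @return A [trajectory()].
#' @export
simulate_fold_minimal <- function(cfg, y0, x0 = NULL, seed = cfg$seed) {
  stopifnot("minimal model requires cfg$cubic = FALSE" = !cfg$cubic)
  simulate_fold(cfg, y0 = y0, x0 = x0, seed = seed)
}

#' Simulate a dot-stimulus fold-transition trajectory
#'
#' Draws a transition time `t*` uniformly from `cfg$tstar_range`, initializes
#' the slow variable at `y(0) = -epsilon * t*` so that it crosses zero exactly
#' at `t*`, integrates the cubic fold map, detrends the result so the
#' pre-transition dot fluctuates around the origin (see
#' [detrend_trajectory()]), and multiplies by a random direction (+1/-1 with
#' equal probability).
#'
#' @inheritParams simulate_fold
#' @param detrend Logical; apply the detrend step (default `TRUE`).
#' @return A detrended, direction-randomized [trajectory()] of kind `"fold"`.
#' @export
simulate_fold_exp3 <- function(cfg, seed = cfg$seed, detrend = TRUE) {
  stopifnot("dot-stimulus model requires cfg$cubic = TRUE" = cfg$cubic,
            "cfg$a must be positive" = cfg$a > 0,
            "cfg$epsilon must be positive" = cfg$epsilon > 0)
  if (!is.null(seed)) set.seed(seed)
  tstar <- stats::runif(1, cfg$tstar_range[1], cfg$tstar_range[2])
  direction <- sample(c(-1L, 1L), 1L)
  traj <- simulate_fold(cfg, y0 = -cfg$epsilon * tstar, seed = NULL)
  if (detrend) traj <- detrend_trajectory(traj)
  traj$x <- direction * traj$x
  traj$direction <- direction
  traj$seed <- seed
  traj
}

#' Detrend a fold trajectory
#'
#' Subtracts the quasi-static stable-branch solution `x_s(y(t))` (the fixed
#' point the system tracks before the transition; zero after `y` crosses 0)
#' and then a constant offset chosen so the pre-transition mean is exactly
#' zero. The fluctuations about the branch -- the part carrying the early
#' warning signals -- are preserved, and the post-transition ramp is
#' unchanged apart from the subtracted level.
#'
#' @param traj A [trajectory()] of kind `"fold"` with latent `y` stored.
#' @return The detrended [trajectory()].
#' @export
detrend_trajectory <- function(traj) {
  stopifnot("detrend applies to fold trajectories" = traj$kind == "fold",
            "latent slow variable y required" = !is.null(traj$y))
  pre <- traj$y < 0
  if (!any(pre)) stop("no pre-transition samples to estimate the trend from")
  a <- traj$cfg$a; cubic <- traj$cfg$cubic
  trend <- stable_branch(traj$y, a, cubic)
  resid <- traj$x - trend
  offset <- mean(resid[pre])
  traj$x <- resid - offset
  traj$detrended <- TRUE
  traj
}

#' Simulate an uncorrelated step-function control trajectory
#'
#' The control for the fold-transition stimulus: a Heaviside step of the
#' given amplitude at `tstar`, plus independent zero-mean uniform noise of
#' half-width `noise_amp` at every readout. It matches a fold trajectory's
#' transition time and noise level while carrying no pre-transition
#' correlation structure, hence no early warning signals.
#'
#' @param tstar Step time in seconds.
#' @param amplitude Step height (the post-transition plateau).
#' @param noise_amp Half-width of the uniform readout noise.
#' @param cfg A [sim_config()] supplying `dt` and `duration`.
#' @param seed Optional seed.
#' @return A [trajectory()] of kind `"heaviside"`.
#' @export
simulate_heaviside_control <- function(tstar, amplitude, noise_amp, cfg,
                                       seed = cfg$seed) {
  validate_sim_config(cfg)
  stopifnot("tstar must fall within the trial" =
              tstar >= 0 && tstar <= cfg$duration,
            "noise_amp must be >= 0" = noise_amp >= 0)
  if (!is.null(seed)) set.seed(seed)
  direction <- sample(c(-1L, 1L), 1L)
  n <- floor(cfg$duration / cfg$dt) + 1L
  tt <- (seq_len(n) - 1L) * cfg$dt
  x <- amplitude * as.numeric(tt >= tstar) +
    stats::runif(n, -noise_amp, noise_amp)
  trajectory(tt, direction * x, y = NULL, tstar_true = tstar,
             direction = direction, kind = "heaviside", cfg = cfg,
             seed = seed)
}

#' Generate a matched fold / control stimulus ensemble
#'
#' Simulates `n_per_arm` fold-transition trajectories, then `n_per_arm`
#' Heaviside controls whose step times are matched elementwise to the fold
#' transition times and whose uniform noise half-width is set from the fold
#' arm: the mean pre-transition standard deviation of the detrended fold
#' signal times `sqrt(3)` (so the control noise variance matches the fold
#' arm's mean pre-transition variance). Per-trajectory seeds are derived
#' deterministically from `cfg$seed` for bit-reproducibility.
#'
#' @param cfg A [sim_config()] with a seed set.
#' @param n_per_arm Number of trajectories per arm.
#' @return A list with elements `fold` (list of trajectories), `control`
#'   (list of matched trajectories), `noise_halfwidth`, and `seeds`.
#' @export
generate_exp3_ensemble <- function(cfg, n_per_arm = 100L) {
  stopifnot("n_per_arm must be >= 1" = n_per_arm >= 1)
  base_seed <- if (is.null(cfg$seed)) 1L else cfg$seed
  fold_seeds <- derive_seeds(base_seed, n_per_arm, stream = 1L)
  ctrl_seeds <- derive_seeds(base_seed, n_per_arm, stream = 2L)
  fold <- lapply(seq_len(n_per_arm), function(i)
    simulate_fold_exp3(cfg, seed = fold_seeds[i]))
  pre_sd <- vapply(fold, function(tr) {
    pre <- tr$t < tr$tstar_true
    if (sum(pre) >= 2) stats::sd(tr$x[pre]) else NA_real_
  }, numeric(1))
  halfwidth <- mean(pre_sd, na.rm = TRUE) * sqrt(3)
  control <- lapply(seq_len(n_per_arm), function(i)
    simulate_heaviside_control(fold[[i]]$tstar_true, amplitude = cfg$a,
                               noise_amp = halfwidth, cfg = cfg,
                               seed = ctrl_seeds[i]))
  list(fold = fold, control = control, noise_halfwidth = halfwidth,
       seeds = list(fold = fold_seeds, control = ctrl_seeds))
}

# Deterministic per-unit seed derivation, kept below 2^31.
derive_seeds <- function(base_seed, n, stream = 1L) {
  (as.numeric(base_seed) * 48271 + stream * 1e6 + seq_len(n)) %% 2147483647
}
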