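#' Configuration for synthetic Attacker/Blocker motion-capture trials
#'
#' The generator emulates the statistical structure the analysis pipeline
#' assumes for a dyadic reaching trial recorded at 240 Hz with seven
#' position sensors: six body sensors share a latent motion component --
#' low-amplitude resting fluctuations whose amplitude and correlation time
#' rise at a latent early-warning event, followed by a smooth reach ramp --
#' plus independent per-sensor measurement noise; the Attacker finger and
#' the Blocker finger are quiet channels that start their own ramps at
#' configurable lags. All timing effects are planted with exact ground
#' truth so parameter recovery can be tested:
#' \itemize{
#'   \item body center-of-mass onset leads finger onset by `body_lead` ms;
#'   \item the EWS event (onset of the correlated fluctuation regime) leads
#'     finger onset by `ews_lead` ms plus Gaussian jitter `ews_jitter` ms;
#'   \item the Blocker response starts `blocker_lag` ms after the EWS event,
#'     toward the Attacker's target.
#' }
#' Noise magnitudes are package defaults chosen for a clean separation
#' between the resting noise floor and the 0.05 cm/s onset threshold; no
#' empirical spectra are published for the original recordings, so none are
#' imitated (see the methods vignette).
#'
#' @param rate Sampling rate, Hz.
#' @param duration Trial duration, seconds.
#' @param sensors Body sensor labels (finger channels are separate).
#' @param body_lead Center-of-mass onset lead over finger onset, ms.
#' @param ews_lead EWS-event lead over finger onset, ms.
#' @param ews_jitter SD of the EWS-event timing jitter, ms.
#' @param blocker_lag Blocker response lag after the EWS event, ms.
#' @param sensor_noise Per-sensor, per-axis white position noise SD, cm.
#' @param fluct_sd_rest Resting latent velocity fluctuation SD, cm/s.
#' @param fluct_sd_ews Latent velocity fluctuation SD in the pre-motion
#'   (EWS) regime, cm/s.
#' @param fluct_phi_ews Lag-1 coefficient of the latent fluctuation in the
#'   EWS regime (resting fluctuations are white).
#' @param reach_amplitude Reach distance of the ramp, cm.
#' @param ramp_duration Duration of the minimum-jerk reach ramp, s.
#' @param finger_onset_range Uniform range the finger onset is drawn from, s.
#' @param seed Integer seed.
#' @return An object of class `motion_config`.
#' @export
motion_config <- function(rate = 240, duration = 2.2,
                          sensors = c("head", "torso", "l_shoulder",
                                      "r_shoulder", "elbow", "wrist"),
                          body_lead = 52, ews_lead = 131, ews_jitter = 20,
                          blocker_lag = 300, sensor_noise = 1e-5,
                          fluct_sd_rest = 5e-4, fluct_sd_ews = 6e-3,
                          fluct_phi_ews = 0.75, reach_amplitude = 15,
                          ramp_duration = 0.4,
                          finger_onset_range = c(0.5, 1.5), seed = NULL) {
  cfg <- list(rate = rate, duration = duration, sensors = sensors,
              body_lead = body_lead, ews_lead = ews_lead,
              ews_jitter = ews_jitter, blocker_lag = blocker_lag,
              sensor_noise = sensor_noise, fluct_sd_rest = fluct_sd_rest,
              fluct_sd_ews = fluct_sd_ews, fluct_phi_ews = fluct_phi_ews,
              reach_amplitude = reach_amplitude,
              ramp_duration = ramp_duration,
              finger_onset_range = as.numeric(finger_onset_range),
              seed = seed)
  stopifnot(
    "rate must be positive" = rate > 0,
    "body_lead must be >= 0" = body_lead >= 0,
    "noise and fluctuation SDs must be >= 0" =
      all(c(sensor_noise, fluct_sd_rest, fluct_sd_ews) >= 0),
    "|fluct_phi_ews| must be < 1" = abs(fluct_phi_ews) < 1,
    "leads must fit within the trial" =
      finger_onset_range[1] - (ews_lead + 4 * ews_jitter) / 1000 > 0.1 &&
      finger_onset_range[2] + ramp_duration / 2 < duration &&
      finger_onset_range[2] - (ews_lead / 1000) + blocker_lag / 1000 <
        duration
  )
  class(cfg) <- "motion_config"
  cfg
}

# Minimum-jerk velocity profile: smooth bell starting quadratically at s = 0,
# displacing `amplitude` over `T_ramp`.
minjerk_velocity <- function(s, amplitude, T_ramp) {
  u <- s / T_ramp
  v <- 30 * amplitude / T_ramp * u^2 * (1 - u)^2
  v[u < 0 | u > 1] <- 0
  v
}

# Latent shared velocity fluctuation: white at rest, switching at the EWS
# event to an AR(1) regime with longer correlation time and larger SD.
latent_fluctuation <- function(n, dt, ews_idx, cfg) {
  phi <- cfg$fluct_phi_ews
  innov_ews <- cfg$fluct_sd_ews * sqrt(1 - phi^2)
  u <- numeric(n)
  e <- stats::rnorm(n)
  for (k in seq_len(n)) {
    if (k < ews_idx) {
      u[k] <- cfg$fluct_sd_rest * e[k]
    } else {
      u[k] <- phi * u[max(k - 1L, 1L)] + innov_ews * e[k]
    }
  }
  u
}

#' Generate one synthetic Attacker (+Blocker) trial
#'
#' See [motion_config()] for the generative model. All body sensors carry
#' the shared latent component along the movement axis (axis 1) plus
#' independent 3-D position noise; the remaining axes are pure noise. The
#' finger and Blocker-finger channels are quiet white-fluctuation channels
#' with their own reach ramps.
#'
#' @param cfg A [motion_config()].
#' @param seed Optional seed overriding `cfg$seed`.
#' @return An object of class `sensor_trial`: list with `t`, `pos` (named
#'   list of T x 3 matrices, body sensors plus `finger`), `blocker_finger`
#'   (T x 3), `truth` (list with `tstar_true`, `body_onset_true`,
#'   `finger_onset_true`, `blocker_onset_true`, `direction`), and `cfg`.
#' @export
generate_attacker_trial <- function(cfg, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / cfg$rate
  n <- floor(cfg$duration / dt) + 1L
  tt <- (seq_len(n) - 1L) * dt
  finger_onset <- stats::runif(1, cfg$finger_onset_range[1],
                               cfg$finger_onset_range[2])
  body_onset <- finger_onset - cfg$body_lead / 1000
  ews_t <- finger_onset - cfg$ews_lead / 1000 +
    stats::rnorm(1, 0, cfg$ews_jitter / 1000)
  ews_t <- min(max(ews_t, 0.15), body_onset - 0.01)
  blocker_onset <- ews_t + cfg$blocker_lag / 1000
  direction <- sample(c(-1L, 1L), 1L)

  ews_idx <- which(tt >= ews_t)[1]
  u <- latent_fluctuation(n, dt, ews_idx, cfg)
  v_shared <- u + direction *
    minjerk_velocity(tt - body_onset, cfg$reach_amplitude, cfg$ramp_duration)
  shared_path <- cumsum(v_shared) * dt

  make_channel <- function(axis1) {
    m <- cbind(axis1, 0, 0) +
      matrix(stats::rnorm(3L * n, 0, cfg$sensor_noise), ncol = 3)
    colnames(m) <- c("x", "y", "z")
    m
  }
  pos <- lapply(cfg$sensors, function(s) make_channel(shared_path))
  names(pos) <- cfg$sensors

  v_finger <- stats::rnorm(n, 0, cfg$fluct_sd_rest) + direction *
    minjerk_velocity(tt - finger_onset, cfg$reach_amplitude,
                     cfg$ramp_duration)
  pos$finger <- make_channel(cumsum(v_finger) * dt)

  v_blocker <- stats::rnorm(n, 0, cfg$fluct_sd_rest) + direction *
    minjerk_velocity(tt - blocker_onset, cfg$reach_amplitude,
                     cfg$ramp_duration)
  blocker <- make_channel(cumsum(v_blocker) * dt)

  truth <- list(tstar_true = ews_t, body_onset_true = body_onset,
                finger_onset_true = finger_onset,
                blocker_onset_true = blocker_onset, direction = direction)
  stopifnot(truth$tstar_true <= truth$body_onset_true,
            truth$body_onset_true <= truth$finger_onset_true)
  structure(list(t = tt, pos = pos, blocker_finger = blocker, truth = truth,
                 cfg = cfg, seed = seed),
            class = "sensor_trial")
}

#' @export
print.sensor_trial <- function(x, ...) {
  cat(sprintf(
    "<sensor_trial: %d sensors + finger, %d samples @ %g Hz, onset %.3fs, dir %+d>\n",
    length(x$pos) - 1L, length(x$t), x$cfg$rate,
    x$truth$finger_onset_true, x$truth$direction))
  invisible(x)
}

#' Generate a block of synthetic trials
#'
#' Independent trials with independent onset-time draws; per-trial seeds are
#' derived deterministically from `cfg$seed`, so the same configuration
#' always reproduces the same block.
#'
#' @param cfg A [motion_config()].
#' @param n_trials Number of trials (a recording block is 30).
#' @param block_index Offset for seed derivation, so successive blocks from
#'   one configuration are distinct but reproducible.
#' @return List of `sensor_trial` objects.
#' @export
generate_block <- function(cfg, n_trials = 30L, block_index = 1L) {
  stopifnot("n_trials must be >= 1" = n_trials >= 1)
  base_seed <- if (is.null(cfg$seed)) 1L else cfg$seed
  seeds <- derive_seeds(base_seed, n_trials, stream = 100L + block_index)
  lapply(seq_len(n_trials), function(i)
    generate_attacker_trial(cfg, seed = seeds[i]))
}
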