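#' Run configuration for end-to-end analyses
#'
#' Aggregates every analysis constant of the pipeline: the simulator and
#' motion-generator configurations, the EWS window lengths, and the detector
#' thresholds. Thresholds are unit-bearing: `var_threshold` applies to the
#' first-PC velocity of the synthetic motion trials (cm/s)^2, scaled to the
#' generator's documented fluctuation amplitudes; the dot-stimulus analysis
#' derives its variance-divergence threshold from the ensemble baseline
#' instead (see [exp3_divergence_threshold()]).
#'
#' @param sim A [sim_config()] for the dot-stimulus simulations.
#' @param motion A [motion_config()] for the synthetic capture trials.
#' @param window_ms EWS window length for motion trials, ms; 60 ms is the
#'   least false-positive-prone of the three standard analysis windows
#'   (40/48/60) for the decay-time fold-change rule at 240 Hz.
#' @param exp3_window_ms EWS window length for detection-rate analyses of
#'   the 10 ms-readout dot trajectories, ms (longer: those series are short
#'   and coarsely sampled).
#' @param var_window_ms Variance windows for the scaling analysis, ms.
#' @param ar1_threshold,tau_fold_change,var_threshold Detector thresholds
#'   for motion trials.
#' @param exp3_ar1_threshold AR(1) threshold for the dot-trajectory
#'   detection-rate comparison (higher than the motion default: with few
#'   samples per window the AR(1) estimator is noisy, and the rate
#'   comparison needs a low false-positive level per trial).
#' @param onset_threshold Speed threshold for motion onset, cm/s.
#' @param coverage Density-filter coverage for delta-t regressions.
#' @param blocker_min_ews False-positive rule for Blocker analyses: EWS
#'   times earlier than this (s) are excluded.
#' @param block_size Trials per block for variance-curve averaging.
#' @param n_blocks,trials_per_block Experiment-1 ensemble size.
#' @param n_per_arm Experiment-3 ensemble size per arm.
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), motion = motion_config(),
                       window_ms = 60, exp3_window_ms = 240,
                       var_window_ms = c(40, 48, 60),
                       ar1_threshold = 0.1, tau_fold_change = 0.20,
                       var_threshold = 4e-5, exp3_ar1_threshold = 0.5,
                       onset_threshold = 0.05, coverage = 0.81,
                       blocker_min_ews = 0.2, block_size = 30L,
                       n_blocks = 10L, trials_per_block = 30L,
                       n_per_arm = 100L, seed = 1L) {
  stopifnot(all(c(ar1_threshold, tau_fold_change, var_threshold,
                  onset_threshold) > 0))
  sim$seed <- seed
  motion$seed <- seed
  structure(list(sim = sim, motion = motion, window_ms = window_ms,
                 exp3_window_ms = exp3_window_ms,
                 var_window_ms = var_window_ms,
                 ar1_threshold = ar1_threshold,
                 tau_fold_change = tau_fold_change,
                 var_threshold = var_threshold,
                 exp3_ar1_threshold = exp3_ar1_threshold,
                 onset_threshold = onset_threshold, coverage = coverage,
                 blocker_min_ews = blocker_min_ews,
                 block_size = as.integer(block_size),
                 n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 n_per_arm = as.integer(n_per_arm), seed = seed),
            class = "run_config")
}

#' Per-trial EWS and onset extraction
#'
#' Runs the kinematics and EWS stages on one synthetic capture trial: first
#' PC of the body sensors, first-difference velocity of its projection,
#' windowed EWS statistics and their rise detectors, and the speed-threshold
#' onsets of the body center of mass, the Attacker finger and the Blocker
#' finger.
#'
#' @param trial A `sensor_trial`.
#' @param cfg A [run_config()].
#' @return List of detection times (s; `NA` when a detector never fires):
#'   `ar1_rise`, `tau_rise`, `var_rise`, `body_onset`, `finger_onset`,
#'   `blocker_onset`, plus `truth`.
#' @export
trial_onsets <- function(trial, cfg = run_config()) {
  w <- window_spec(cfg$window_ms, rate = trial$cfg$rate)
  fp <- first_pc(trial)
  vel <- diff(fp$projection) * trial$cfg$rate
  s <- ews_series(vel, w, t = trial$t[-1])
  com <- center_of_mass(trial)
  list(ar1_rise = detect_ar1_rise(s, cfg$ar1_threshold),
       tau_rise = detect_tau_rise(s, cfg$tau_fold_change),
       var_rise = detect_var_rise(s, cfg$var_threshold),
       body_onset = detect_onset(com, t = trial$t,
                                 threshold = cfg$onset_threshold),
       finger_onset = detect_onset(trial$pos$finger, t = trial$t,
                                   threshold = cfg$onset_threshold),
       blocker_onset = blocker_response(trial$blocker_finger,
                                        trial$truth$direction, t = trial$t,
                                        threshold = cfg$onset_threshold),
       truth = trial$truth)
}

#' Run the synthetic Attacker-Blocker analysis end to end
#'
#' Generates `n_blocks` blocks of `trials_per_block` synthetic capture
#' trials, extracts per-trial EWS rise times and motion onsets, and
#' computes: the density-filtered delta-t regression of finger onset on
#' each EWS type; the Blocker regressions with the false-positive rule; the
#' mean center-of-mass lead over finger onset; and the variance-divergence
#' scaling fit over block-averaged curves.
#'
#' @param cfg A [run_config()].
#' @return A nested list report (JSON-serializable) with elements `config`
#'   (seed and sizes), `counts`, `com_lead_ms`, `delta` (per EWS type),
#'   `blocker_delta`, `scaling`, and `pc_loadings`.
#' @export
run_experiment1 <- function(cfg = run_config()) {
  trials <- unlist(lapply(seq_len(cfg$n_blocks), function(b)
    generate_block(cfg$motion, cfg$trials_per_block, block_index = b)),
    recursive = FALSE)
  res <- lapply(trials, trial_onsets, cfg = cfg)
  get <- function(f) vapply(res, function(r) r[[f]], numeric(1))
  finger <- get("finger_onset"); body <- get("body_onset")
  blocker <- get("blocker_onset")
  delta_of <- function(ewst, onset, min_ews = NULL) {
    dr <- delta_regression(ewst, onset, coverage = cfg$coverage,
                           min_ews_time = min_ews)
    list(slope = dr$slope, intercept_ms = 1000 * dr$intercept,
         intercept_se_ms = 1000 * dr$intercept_se,
         mean_diff_ms = 1000 * dr$mean_diff,
         retained_fraction = dr$retained_fraction, n_used = dr$n_used)
  }
  lead <- 1000 * (finger - body)
  lead <- lead[is.finite(lead)]
  sensor_pct <- rowMeans(vapply(trials, function(tr)
    as.numeric(first_pc(tr)$sensor_pct), numeric(length(cfg$motion$sensors))))
  names(sensor_pct) <- cfg$motion$sensors

  scaling <- exp1_scaling(trials, cfg)
  list(
    config = list(seed = cfg$seed, n_trials = length(trials),
                  n_blocks = cfg$n_blocks,
                  trials_per_block = cfg$trials_per_block,
                  window_ms = cfg$window_ms),
    counts = list(
      n_finger_onset = sum(is.finite(finger)),
      n_body_onset = sum(is.finite(body)),
      n_blocker_onset = sum(is.finite(blocker)),
      n_ar1_rise = sum(is.finite(get("ar1_rise"))),
      n_tau_rise = sum(is.finite(get("tau_rise"))),
      n_var_rise = sum(is.finite(get("var_rise")))),
    com_lead_ms = list(mean = mean(lead),
                       se = stats::sd(lead) / sqrt(length(lead)),
                       n = length(lead)),
    delta = list(
      ar1 = delta_of(get("ar1_rise"), finger),
      tau = delta_of(get("tau_rise"), finger),
      var = delta_of(get("var_rise"), finger)),
    blocker_delta = list(
      ar1 = delta_of(get("ar1_rise"), blocker, cfg$blocker_min_ews),
      tau = delta_of(get("tau_rise"), blocker, cfg$blocker_min_ews)),
    scaling = scaling,
    pc_loadings_pct = as.list(sensor_pct))
}

# Variance-divergence scaling on motion trials: first-PC velocity, windowed
# variance, per-trial curve extraction synchronized on the var_threshold
# crossing, block averaging, anchored pre-divergence power-law fits.
exp1_scaling <- function(trials, cfg) {
  w <- window_spec(48, rate = trials[[1]]$cfg$rate)
  curves <- lapply(trials, function(tr) {
    fp <- first_pc(tr)
    vel <- diff(fp$projection) * tr$cfg$rate
    vs <- windowed_variance(vel, w, t = tr$t[-1])
    extract_divergence_curve(vs, cfg$var_threshold)
  })
  blocks <- average_block_curves(curves, cfg$block_size)
  pre <- lapply(blocks, function(b) b[b$rel_t <= 1e-9, ])
  res <- median_divergence_exponent(pre, anchor = "end")
  list(median_n = res$median_n, n_curves = length(blocks),
       n_kept = res$n_kept,
       n_excluded_trials = attr(blocks, "n_excluded"))
}

#' Ensemble divergence threshold for dot-stimulus trajectories
#'
#' The variance-divergence synchronization threshold for simulated
#' trajectories: the maximal windowed variance observed within the first
#' `baseline_window` seconds across all trials of the ensemble. (The
#' absolute threshold used for motion-capture velocity is unit-specific and
#' does not transfer to model units.)
#'
#' @param var_series_list List of windowed-variance data frames.
#' @param baseline_window Length of the initial baseline period, s.
#' @return The threshold (squared signal units).
#' @export
exp3_divergence_threshold <- function(var_series_list,
                                      baseline_window = 0.100) {
  base <- unlist(lapply(var_series_list, function(v)
    v$var[v$t <= baseline_window]))
  stopifnot("no baseline windows found" = length(base) > 0)
  max(base, na.rm = TRUE)
}

#' Variance-divergence scaling analysis of a fold-trajectory ensemble
#'
#' The full scaling pipeline for simulated fold-transition trajectories:
#' windowed variance of each (detrended) trajectory at each window length;
#' per-trial extraction of the 100 ms before and after the
#' variance-divergence point (ensemble-baseline threshold); block averaging
#' of 30 curves synchronized on the divergence point; anchored power-law
#' fits (48 ms sub-window ending at the divergence point) of the
#' pre-divergence segment; median exponent over fits with |n| < 1.5, pooled
#' across the window lengths.
#'
#' @param ensemble List of `trajectory` objects (fold arm).
#' @param cfg A [run_config()] (uses `var_window_ms` and `block_size`).
#' @return List with `median_n` (pooled), `by_window` (per window length),
#'   `n_values`, `n_kept`, `n_curves`.
#' @export
exp3_scaling <- function(ensemble, cfg = run_config()) {
  rate <- 1 / ensemble[[1]]$cfg$dt
  by_window <- list()
  all_n <- c()
  n_curves <- 0L
  for (wm in cfg$var_window_ms) {
    w <- window_spec(wm, rate = rate)
    vs <- lapply(ensemble, function(tr) windowed_variance(tr$x, w, t = tr$t))
    thr <- exp3_divergence_threshold(vs)
    curves <- lapply(vs, function(v) extract_divergence_curve(v, thr))
    blocks <- average_block_curves(curves, cfg$block_size)
    pre <- lapply(blocks, function(b) b[b$rel_t <= 1e-9, ])
    res <- median_divergence_exponent(pre, anchor = "end")
    by_window[[as.character(wm)]] <- list(median_n = res$median_n,
                                          n_kept = res$n_kept,
                                          threshold = thr)
    all_n <- c(all_n, res$n_values)
    n_curves <- n_curves + length(blocks)
  }
  kept <- all_n[!is.na(all_n) & abs(all_n) < 1.5]
  list(median_n = stats::median(kept), by_window = by_window,
       n_values = all_n, n_kept = length(kept), n_curves = n_curves)
}

#' Run the dot-stimulus experiment end to end
#'
#' Generates a matched fold/control ensemble, computes per-trajectory EWS
#' series and rise detections, per-arm pre-transition detection rates, the
#' variance-divergence scaling fit for the fold arm, and a simulated-observer
#' reaction-time comparison: the observer responds at the earliest early
#' warning cue, or at the dot's displacement crossing half the plateau
#' amplitude when no cue fires -- an idealized readout showing that the fold
#' arm carries usable information earlier (human reaction times are not
#' modeled).
#'
#' @param cfg A [run_config()].
#' @return A nested list report with `config`, `rates` (per arm and
#'   detector), `scaling`, and `rt` (simulated-observer comparison).
#' @export
run_experiment3 <- function(cfg = run_config()) {
  stopifnot("n_per_arm must be >= 1" = cfg$n_per_arm >= 1)
  ens <- generate_exp3_ensemble(cfg$sim, cfg$n_per_arm)
  w <- window_spec(cfg$exp3_window_ms, rate = 1 / cfg$sim$dt)
  arm_stats <- function(arm) {
    lapply(arm, function(tr) {
      s <- ews_series(tr$x, w, t = tr$t)
      list(s = s, tstar = tr$tstar_true)
    })
  }
  fold <- arm_stats(ens$fold)
  ctrl <- arm_stats(ens$control)
  # Baseline period for the rate analysis: window centers early enough that
  # every window lies before the earliest possible transition (350 ms).
  # Each arm's variance detector is referenced to that arm's own resting
  # baseline (the control is amplitude-matched to the fold arm's mean
  # pre-transition fluctuation, so a common absolute threshold would only
  # reflect that construction, not a rise).
  baseline_win <- cfg$sim$tstar_range[1] - cfg$exp3_window_ms / 2000
  var_thr <- exp3_divergence_threshold(lapply(fold, function(f) f$s),
                                       baseline_window = baseline_win)
  var_thr_ctrl <- exp3_divergence_threshold(lapply(ctrl, function(f) f$s),
                                            baseline_window = baseline_win)
  # A detection counts as pre-transition only when the firing window lies
  # wholly before t*: window centers within half a window of t* already
  # contain post-transition samples.
  margin <- cfg$exp3_window_ms / 2000
  rate_of <- function(arm, detect) {
    mean(vapply(arm, function(a) {
      tt <- detect(a$s)
      is.finite(tt) && tt < a$tstar - margin
    }, logical(1)))
  }
  rates <- list(
    ar1 = list(
      fold = rate_of(fold, function(s) detect_ar1_rise(s, cfg$exp3_ar1_threshold)),
      control = rate_of(ctrl, function(s) detect_ar1_rise(s, cfg$exp3_ar1_threshold))),
    tau = list(
      fold = rate_of(fold, function(s) detect_tau_rise(s, cfg$tau_fold_change)),
      control = rate_of(ctrl, function(s) detect_tau_rise(s, cfg$tau_fold_change))),
    var = list(
      fold = rate_of(fold, function(s) detect_var_rise(s, var_thr)),
      control = rate_of(ctrl, function(s) detect_var_rise(s, var_thr_ctrl))))
  # Simulated observer: responds at the earliest of the three EWS cues
  # (AR(1), decay-time and variance rises, at the detection-rate thresholds)
  # or, failing those, at the displacement crossing half the plateau
  # amplitude. An idealized reader of the early warning signals: it
  # demonstrates that the fold arm carries usable information earlier, not
  # how humans time their responses.
  observer_rt <- function(arm_stats, arm_traj, arm_thr) {
    vapply(seq_along(arm_traj), function(i) {
      tr <- arm_traj[[i]]
      s <- arm_stats[[i]]$s
      idx <- which(abs(tr$x) > cfg$sim$a / 2)
      t_move <- if (length(idx) == 0) Inf else tr$t[idx[1]]
      out <- min(t_move,
                 detect_ar1_rise(s, cfg$exp3_ar1_threshold),
                 detect_tau_rise(s, cfg$tau_fold_change),
                 detect_var_rise(s, arm_thr), na.rm = TRUE)
      if (is.finite(out)) out else NA_real_
    }, numeric(1))
  }
  rt_fold <- 1000 * observer_rt(fold, ens$fold, var_thr)
  rt_ctrl <- 1000 * observer_rt(ctrl, ens$control, var_thr_ctrl)
  rtc <- rt_compare(rt_fold[is.finite(rt_fold)], rt_ctrl[is.finite(rt_ctrl)])
  list(
    config = list(seed = cfg$seed, n_per_arm = cfg$n_per_arm,
                  exp3_window_ms = cfg$exp3_window_ms,
                  noise_halfwidth = ens$noise_halfwidth),
    rates = rates,
    scaling = exp3_scaling(ens$fold, cfg),
    rt = list(mean_diff_ms = mean(rt_ctrl, na.rm = TRUE) -
                mean(rt_fold, na.rm = TRUE),
              u_stat = rtc$u_stat, p_mw = rtc$p_mw,
              effect_size = rtc$effect_size,
              ks_stat = rtc$ks_stat, p_ks = rtc$p_ks,
              decile_diffs_ms = rtc$decile_diffs))
}
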