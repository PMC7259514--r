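#' Sliding-window specification for EWS statistics
#'
#' @param length_ms Window duration in milliseconds (40, 48 and 60 ms are the
#'   standard analysis choices).
#' @param rate Sampling rate in Hz.
#' @param stride_ms Step between successive windows in milliseconds; the
#'   default advances one sample.
#' @return An object of class `window_spec` with the derived sample counts.
#' @export
window_spec <- function(length_ms = 40, rate = 240, stride_ms = NULL) {
  n <- as.integer(round(length_ms * rate / 1000))
  stride <- if (is.null(stride_ms)) 1L
            else max(1L, as.integer(round(stride_ms * rate / 1000)))
  stopifnot("window must span at least 2 samples" = n >= 2,
            "rate must be positive" = rate > 0)
  structure(list(length_ms = length_ms, rate = rate, n = n, stride = stride),
            class = "window_spec")
}

window_starts <- function(N, w) {
  if (N < w$n) stop("series shorter than one window")
  seq.int(1L, N - w$n + 1L, by = w$stride)
}

#' Windowed lag-1 autocorrelation
#'
#' For each window of `w$n` samples the statistic is
#' \deqn{AR(1) = \sum_i (v_i - v_0)(v_{i-1} - v_0) / \sum_i (v_i - v_0)^2}
#' with \eqn{v_0} the window mean, the sums running over the window. A
#' window with zero denominator (constant signal) yields `NA`. Rising AR(1)
#' is the classic signature of critical slowing down: fluctuations decay
#' more slowly as a system approaches a bifurcation, so successive samples
#' resemble each other more.
#'
#' @param v Numeric series (typically a velocity trace or a detrended
#'   trajectory).
#' @param w A [window_spec()].
#' @param t Optional sample times; defaults to `(0:(N-1))/rate`.
#' @return Data frame with window-center times `t` and `ar1`.
#' @export
windowed_ar1 <- function(v, w, t = NULL) {
  stopifnot("AR(1) needs windows of >= 4 samples" = w$n >= 4)
  st <- window_starts(length(v), w)
  tt <- window_center_times(t, v, w, st)
  ar1 <- vapply(st, function(s) ar1_window(v[s:(s + w$n - 1L)]), numeric(1))
  data.frame(t = tt, ar1 = ar1)
}

ar1_window <- function(x) {
  v0 <- mean(x)
  d <- x - v0
  den <- sum(d^2)
  if (den <= 0) return(NA_real_)
  n <- length(x)
  sum(d[-1] * d[-n]) / den
}

#' Windowed autocorrelation decay time
#'
#' For each window, the normalized autocovariance at lag `l` is
#' \deqn{R(l) = \sum_i (v_i - v_0)(v_{i-l} - v_0) / \sum_i (v_i - v_0)^2,}
#' so `R(0) = 1`, and the decay time is the first integer lag at which
#' `R(l) <= 1/e`, reported in milliseconds (`l / rate * 1000`). If the
#' autocorrelation never decays below `1/e` within the window, the value is
#' `NA`. The decay time lengthens on approach to a critical transition
#' (critical slowing down).
#'
#' @inheritParams windowed_ar1
#' @return Data frame with window-center times `t` and `tau_ms`.
#' @export
autocorr_decay_time <- function(v, w, t = NULL) {
  stopifnot("decay time needs windows of >= 4 samples" = w$n >= 4)
  st <- window_starts(length(v), w)
  tt <- window_center_times(t, v, w, st)
  tau <- vapply(st, function(s)
    tau_window(v[s:(s + w$n - 1L)], w$rate), numeric(1))
  data.frame(t = tt, tau_ms = tau)
}

tau_window <- function(x, rate) {
  v0 <- mean(x)
  d <- x - v0
  den <- sum(d^2)
  if (den <= 0) return(NA_real_)
  n <- length(x)
  thr <- exp(-1)
  for (l in seq_len(n - 1L)) {
    Rl <- sum(d[(l + 1L):n] * d[1:(n - l)]) / den
    if (Rl <= thr) return(l / rate * 1000)
  }
  NA_real_
}

#' Windowed variance
#'
#' Unbiased sample variance (divisor `n - 1`) per sliding window. Near a
#' fold transition the variance of the fast variable diverges as
#' `(t* - t)^(-1/2)`.
#'
#' @inheritParams windowed_ar1
#' @return Data frame with window-center times `t` and `var`.
#' @export
windowed_variance <- function(v, w, t = NULL) {
  st <- window_starts(length(v), w)
  tt <- window_center_times(t, v, w, st)
  va <- vapply(st, function(s)
    stats::var(v[s:(s + w$n - 1L)]), numeric(1))
  data.frame(t = tt, var = va)
}

window_center_times <- function(t, v, w, starts) {
  if (is.null(t)) t <- (seq_along(v) - 1L) / w$rate
  stopifnot(length(t) == length(v))
  t[starts] + (w$n - 1L) / (2 * w$rate)
}

#' Compute the full EWS series for a signal
#'
#' Convenience wrapper returning all three windowed early-warning statistics
#' aligned on common window-center times.
#'
#' @inheritParams windowed_ar1
#' @return An object of class `ews_series`: a data frame with columns `t`,
#'   `ar1`, `tau_ms`, `var`.
#' @export
ews_series <- function(v, w, t = NULL) {
  a <- windowed_ar1(v, w, t)
  ta <- autocorr_decay_time(v, w, t)
  va <- windowed_variance(v, w, t)
  out <- data.frame(t = a$t, ar1 = a$ar1, tau_ms = ta$tau_ms, var = va$var)
  class(out) <- c("ews_series", "data.frame")
  out
}

#' Detect the sharp rise of the AR(1) curve
#'
#' The rise time is the center of the first window whose AR(1) exceeds the
#' threshold (default 0.1).
#'
#' @param s An [ews_series()] or a data frame with columns `t` and `ar1`.
#' @param threshold Detection threshold.
#' @return The detection time in the units of `s$t`, or `NA_real_` if the
#'   curve never crosses.
#' @export
detect_ar1_rise <- function(s, threshold = 0.1) {
  stopifnot(nrow(s) > 0)
  idx <- which(!is.na(s$ar1) & s$ar1 > threshold)
  if (length(idx) == 0) NA_real_ else s$t[idx[1]]
}

#' Detect the sharp rise of the autocorrelation decay time
#'
#' The rise time is the center of the first window whose decay time exceeds
#' the preceding window's by more than `fold_change` (default 20%). The
#' fold-change rule filters out noisy detection events while remaining
#' sensitive to the genuine lengthening of the decay time near a transition.
#'
#' @param s An [ews_series()] or a data frame with columns `t` and `tau_ms`.
#' @param fold_change Minimum relative increase between consecutive windows.
#' @return Detection time or `NA_real_`.
#' @export
detect_tau_rise <- function(s, fold_change = 0.20) {
  tau <- s$tau_ms
  ok <- which(!is.na(tau))
  if (length(ok) < 2) return(NA_real_)
  for (j in seq_len(nrow(s) - 1L)) {
    if (is.na(tau[j]) || is.na(tau[j + 1L])) next
    if (tau[j + 1L] / tau[j] - 1 > fold_change) return(s$t[j + 1L])
  }
  NA_real_
}

#' Detect the sharp rise of the variance
#'
#' The rise time is the center of the first window whose variance exceeds
#' the threshold. The default 1.5e-4 corresponds to velocity in cm/s as
#' recorded in the motion-capture experiments; the threshold is unit-bearing
#' and must be rescaled for signals in other units (see the package
#' vignette).
#'
#' @param s An [ews_series()] or a data frame with columns `t` and `var`.
#' @param threshold Detection threshold, in squared signal units.
#' @return Detection time or `NA_real_`.
#' @export
detect_var_rise <- function(s, threshold = 1.5e-4) {
  stopifnot(nrow(s) > 0)
  idx <- which(!is.na(s$var) & s$var > threshold)
  if (length(idx) == 0) NA_real_ else s$t[idx[1]]
}
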