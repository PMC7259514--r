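test_that("windowed AR(1) matches hand-computed values", {
  w <- window_spec(length_ms = 10 * 1000 / 240, rate = 240)  # 10 samples
  alt <- rep(c(1, -1), 5)
  s <- windowed_ar1(alt, w)
  expect_equal(nrow(s), 1L)
  expect_equal(s$ar1, -9 / 10)
  # constant window: zero denominator
  expect_true(is.na(windowed_ar1(rep(3, 10), w)$ar1))
})

test_that("AR(1) estimate recovers the coefficient of a long AR process", {
  set.seed(5)
  n <- 20000
  x <- as.numeric(stats::arima.sim(list(ar = 0.8), n))
  w <- window_spec(length_ms = n * 1000 / 240, rate = 240)
  s <- windowed_ar1(x, w)
  expect_equal(s$ar1, 0.8, tolerance = 0.02)
})

test_that("decay time follows the analytic geometric decay", {
  # AR coefficient 0.9: 0.9^10 < 1/e < 0.9^9, so the crossing lag is 10
  set.seed(8)
  n <- 50000
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), n))
  w <- window_spec(length_ms = n * 1000 / 1000, rate = 1000)
  s <- autocorr_decay_time(x, w)
  expect_equal(s$tau_ms, 10 * 1000 / 1000)  # 10 samples, in ms at 1 kHz

  # coefficient exactly 1/e: crossing at lag 1 in expectation; the estimate
  # sits on the threshold boundary, so sampling noise can push it to lag 2
  set.seed(9)
  y <- as.numeric(stats::arima.sim(list(ar = exp(-1)), n))
  sy <- autocorr_decay_time(y, w)
  expect_lte(sy$tau_ms, 2)
})

test_that("white-noise windows mostly decay within one lag", {
  set.seed(3)
  w <- window_spec(50, rate = 240)  # 12 samples
  x <- stats::rnorm(3000)
  s <- autocorr_decay_time(x, w)
  one_lag <- mean(s$tau_ms == 1 / 240 * 1000, na.rm = TRUE)
  expect_gt(one_lag, 0.5)
})

test_that("windowed variance is the unbiased sample variance", {
  w2 <- window_spec(length_ms = 2 * 1000 / 240, rate = 240)
  expect_equal(windowed_variance(c(0, 2), w2)$var, 2)
  expect_equal(windowed_variance(rep(1, 2), w2)$var, 0)
  set.seed(4)
  x <- stats::rnorm(50000)
  w <- window_spec(length_ms = 50000 * 1000 / 240, rate = 240)
  expect_equal(windowed_variance(x, w)$var, 1, tolerance = 0.02)
})

test_that("vectorized statistics match naive double-loop oracles", {
  set.seed(11)
  w <- window_spec(40, rate = 240)
  for (rep in 1:25) {
    x <- stats::rnorm(w$n, sd = stats::runif(1, 0.1, 10))
    s <- ews_series(x, w)
    expect_equal(s$ar1, oracle_ar1(x), tolerance = 1e-12)
    expect_equal(s$tau_ms, oracle_tau(x, w$rate), tolerance = 1e-12)
    expect_equal(s$var, oracle_var(x), tolerance = 1e-12)
  }
})

test_that("EWS statistics transform correctly under shift and scale", {
  set.seed(12)
  w <- window_spec(60, rate = 240)
  x <- stats::rnorm(100)
  s0 <- ews_series(x, w)
  s_shift <- ews_series(x + 7.3, w)
  s_scale <- ews_series(2.5 * x, w)
  expect_equal(s_shift$ar1, s0$ar1, tolerance = 1e-9)
  expect_equal(s_shift$tau_ms, s0$tau_ms)
  expect_equal(s_shift$var, s0$var, tolerance = 1e-9)
  expect_equal(s_scale$ar1, s0$ar1, tolerance = 1e-9)
  expect_equal(s_scale$tau_ms, s0$tau_ms)
  expect_equal(s_scale$var, 2.5^2 * s0$var, tolerance = 1e-9)
})

test_that("AR(1) estimates respect the small-sample bound", {
  set.seed(13)
  w <- window_spec(40, rate = 240)
  x <- stats::rnorm(2000)
  s <- windowed_ar1(x, w)
  expect_true(all(abs(s$ar1) <= 1 + 2 / w$n, na.rm = TRUE))
})

test_that("rise detectors fire at the documented thresholds", {
  s <- data.frame(t = 1:4, ar1 = c(-0.2, 0.05, 0.12, 0.4))
  expect_equal(detect_ar1_rise(s, 0.1), 3)
  expect_true(is.na(detect_ar1_rise(
    data.frame(t = 1:3, ar1 = c(-0.2, 0, 0.05)), 0.1)))

  s <- data.frame(t = 1:5, tau_ms = c(5, 5, 5, 6.5, 6.5))
  expect_equal(detect_tau_rise(s, 0.2), 4)  # 30% rise fires
  expect_true(is.na(detect_tau_rise(
    data.frame(t = 1:2, tau_ms = c(5, 5.9)), 0.2)))  # 18% does not

  s <- data.frame(t = 1:3, var = c(1e-4, 1.2e-4, 1.6e-4))
  expect_equal(detect_var_rise(s, 1.5e-4), 3)
  expect_true(is.na(detect_var_rise(
    data.frame(t = 1:3, var = c(1e-4, 1.2e-4, 1.4e-4)), 1.5e-4)))
})

test_that("detectors skip missing windows and survive all-NA series", {
  s <- data.frame(t = 1:5, tau_ms = c(NA, 5, NA, 5, 7))
  expect_equal(detect_tau_rise(s, 0.2), 5)
  expect_true(is.na(detect_tau_rise(
    data.frame(t = 1:3, tau_ms = rep(NA_real_, 3)))))
  expect_true(is.na(detect_ar1_rise(
    data.frame(t = 1:3, ar1 = rep(NA_real_, 3)))))
})

test_that("window bookkeeping is validated", {
  expect_error(window_spec(2, rate = 240), "2 samples")
  w <- window_spec(40, rate = 240)
  expect_error(windowed_ar1(stats::rnorm(5), w), "shorter")
  expect_equal(w$n, round(40 * 240 / 1000))  # 40 ms at 240 Hz -> 10 samples
})

test_that("fold trajectories show AR(1) rises before t* more often than controls", {
  cfg <- exp3_cfg(seed = 21)
  ens <- generate_exp3_ensemble(cfg, n_per_arm = 40)
  w <- window_spec(240, rate = 100)
  margin <- 0.12
  rate_before <- function(arm, thr) {
    mean(vapply(arm, function(tr) {
      tt <- detect_ar1_rise(windowed_ar1(tr$x, w, t = tr$t), thr)
      is.finite(tt) && tt < tr$tstar_true - margin
    }, logical(1)))
  }
  expect_gt(rate_before(ens$fold, 0.5), 0.8)
  expect_lt(rate_before(ens$control, 0.5), 0.2)
})

test_that("decay-time rises before t* are more frequent on fold than control arms", {
  cfg <- exp3_cfg(seed = 22)
  ens <- generate_exp3_ensemble(cfg, n_per_arm = 40)
  w <- window_spec(240, rate = 100)
  margin <- 0.12
  rate_before <- function(arm) {
    mean(vapply(arm, function(tr) {
      tt <- detect_tau_rise(autocorr_decay_time(tr$x, w, t = tr$t), 0.2)
      is.finite(tt) && tt < tr$tstar_true - margin
    }, logical(1)))
  }
  expect_gt(rate_before(ens$fold), rate_before(ens$control))
})
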