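test_that("density filter retains the requested coverage on a Gaussian cloud", {
  set.seed(30)
  x <- stats::rnorm(1000); y <- stats::rnorm(1000)
  for (cov in c(0.96, 0.81, 0.60)) {
    mask <- density_filter(x, y, coverage = cov)
    expect_lt(abs(mean(mask) - cov), 0.03)
  }
  # full coverage keeps everything
  expect_true(all(density_filter(x, y, coverage = 1)))
})

test_that("density filter mask is invariant under affine axis rescaling", {
  set.seed(31)
  x <- stats::rnorm(300); y <- x + stats::rnorm(300, 0, 0.5)
  m0 <- density_filter(x, y, 0.81)
  m1 <- density_filter(1000 * x - 7, 0.01 * y + 3, 0.81)
  expect_identical(as.logical(m0), as.logical(m1))
})

test_that("degenerate clouds fall back to retaining all points", {
  mask <- density_filter(rep(1, 20), seq_len(20), 0.81)
  expect_true(all(mask))
  expect_true(attr(mask, "degenerate"))
})

test_that("delta regression recovers exact offsets", {
  set.seed(32)
  ews <- stats::runif(100, 0.5, 1.5)
  dr <- delta_regression(ews, ews + 0.131, coverage = 0.81)
  expect_equal(dr$slope, 1, tolerance = 1e-9)
  expect_equal(dr$intercept, 0.131, tolerance = 1e-9)
  # identity: zero intercept
  dr0 <- delta_regression(ews, ews, coverage = 0.81)
  expect_equal(dr0$intercept, 0, tolerance = 1e-9)
})

test_that("delta regression intercept is equivariant under onset shifts", {
  set.seed(33)
  ews <- stats::runif(200, 0.5, 1.5)
  onset <- ews + 0.1 + stats::rnorm(200, 0, 0.02)
  d1 <- delta_regression(ews, onset, 0.81)
  d2 <- delta_regression(ews, onset + 0.05, 0.81)
  expect_equal(d2$intercept - d1$intercept, 0.05, tolerance = 1e-9)
  expect_equal(d2$slope, d1$slope, tolerance = 1e-9)
})

test_that("the false-positive rule excludes early EWS times", {
  set.seed(34)
  ews <- c(stats::runif(50, 0.5, 1.5), rep(0.05, 10))
  onset <- c(stats::runif(50, 0.5, 1.5) + 0.3, stats::runif(10, 0.5, 1.5))
  dr <- delta_regression(ews, onset, coverage = 1,
                         min_ews_time = 0.2)
  expect_equal(dr$n_used, 50L)
  expect_error(delta_regression(rep(0.1, 12), rep(1, 12), 0.81,
                                min_ews_time = 0.2), "pairs")
})

test_that("identical reaction-time arms compare as null", {
  x <- c(300, 310, 320, 330, 340, 350)
  rc <- rt_compare(x, x)
  expect_equal(rc$u_stat, length(x)^2 / 2)
  expect_equal(rc$effect_size, 0)
  expect_equal(rc$decile_diffs, rep(0, 9))
})

test_that("a constant shift moves every decile by that shift", {
  set.seed(35)
  a <- stats::rnorm(80, 500, 60)
  rc <- rt_compare(a, a + 100)
  expect_equal(rc$decile_diffs, rep(100, 9), tolerance = 1e-9)
  expect_lt(rc$p_mw, 0.01)
  expect_gt(rc$effect_size, 0)  # positive: arm a is faster
})

test_that("rank tests are invariant under common monotone transforms", {
  set.seed(36)
  a <- stats::rgamma(60, 4, 0.01); b <- a + 80
  r1 <- rt_compare(a, b)
  r2 <- rt_compare(log(a), log(b))
  expect_equal(r1$u_stat, r2$u_stat)
  expect_equal(r1$ks_stat, r2$ks_stat)
})

test_that("KS p-values are calibrated under the null", {
  set.seed(37)
  ps <- replicate(120, {
    rt_compare(stats::rnorm(200), stats::rnorm(200))$p_ks
  })
  # uniform p-values: mean 0.5 +/- 3 * sqrt(1/12/120)
  expect_lt(abs(mean(ps) - 0.5), 3 * sqrt(1 / 12 / 120))
  expect_lt(mean(ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
})

test_that("tied-only input takes the degenerate path", {
  rc <- rt_compare(rep(5, 6), rep(5, 7))
  expect_true(rc$ties_degenerate)
  expect_equal(rc$p_mw, 1)
})

test_that("Harrell-Davis deciles track the true quantiles", {
  set.seed(38)
  x <- stats::rnorm(5000)
  hd <- ewsmotion:::hd_quantile(x, c(0.1, 0.5, 0.9))
  expect_equal(hd, stats::qnorm(c(0.1, 0.5, 0.9)), tolerance = 0.06)
})
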