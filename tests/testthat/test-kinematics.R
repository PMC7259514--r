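make_pos <- function(...) {
  lst <- list(...)
  lapply(lst, function(m) {
    m <- as.matrix(m)
    if (ncol(m) == 1) m <- cbind(m, 0, 0)
    colnames(m) <- c("x", "y", "z")
    m
  })
}

test_that("identical noiseless sensors load the first PC equally", {
  path <- cumsum(c(0, stats::rnorm(99)))
  pos <- make_pos(a = path, b = path, c = path)
  fp <- first_pc(pos, exclude = character(0))
  expect_equal(unname(as.numeric(fp$sensor_pct)), rep(100 / 3, 3),
               tolerance = 1e-9)
  expect_false(fp$fallback)
})

test_that("first PC aligns with the larger-variance sensor in a 2-sensor toy", {
  set.seed(2)
  n <- 2000
  a <- cbind(stats::rnorm(n, sd = 3), 0, 0)  # motion along x
  b <- cbind(0, stats::rnorm(n, sd = 1), 0)  # orthogonal, smaller
  fp <- first_pc(make_pos(a = a, b = b), exclude = character(0))
  # closed-form 2-D PCA: diagonal covariance, leading eigenvector is the
  # coordinate axis with the larger variance
  pct <- fp$loadings_pct
  expect_gt(pct[["a.x"]], 95)
  expect_lt(sum(pct) - pct[["a.x"]], 5)
  expect_equal(sum(pct), 100, tolerance = 1e-9)
})

test_that("first PC projection sign is fixed toward the net displacement", {
  path <- c(seq(0, 0, length.out = 50), seq(0, 5, length.out = 50))
  pos <- make_pos(a = path, b = path + 0.01)
  fp <- first_pc(pos, exclude = character(0))
  expect_gt(fp$projection[100] - fp$projection[1], 0)
  # reversed motion projects identically up to sign convention
  fp2 <- first_pc(make_pos(a = -path, b = -path - 0.01),
                  exclude = character(0))
  expect_equal(fp2$projection, fp$projection, tolerance = 1e-9)
})

test_that("degenerate (constant) input falls back to the center of mass", {
  pos <- make_pos(a = rep(1, 10), b = rep(2, 10))
  fp <- first_pc(pos, exclude = character(0))
  expect_true(fp$fallback)
  expect_equal(length(fp$projection), 10L)
})

test_that("center of mass averages the body sensors", {
  path <- cumsum(stats::rnorm(20))
  pos <- make_pos(a = path, b = path)
  expect_equal(center_of_mass(pos, exclude = character(0))[, 1], path)
  pos2 <- make_pos(a = path, b = -path)
  expect_equal(center_of_mass(pos2, exclude = character(0))[, 1],
               rep(0, 20))
})

test_that("onset detection obeys its contract", {
  # static series: no onset
  expect_true(is.na(detect_onset(rep(1, 50), dt = 1 / 240)))
  # ramp of 0.1 cm/s starting at t0: detected one sample after t0
  dt <- 1 / 240
  t0 <- 50 * dt
  tt <- (0:99) * dt
  pos <- ifelse(tt >= t0, (tt - t0) * 0.1, 0)
  expect_equal(detect_onset(pos, t = tt, threshold = 0.05), t0 + dt)
  # translation invariance
  expect_equal(detect_onset(pos + 13.7, t = tt, threshold = 0.05), t0 + dt)
})

test_that("onset time is monotone in the threshold", {
  set.seed(6)
  dt <- 1 / 240
  tt <- (0:199) * dt
  pos <- cumsum(c(0, stats::rnorm(199, 0, 1e-4))) +
    ifelse(tt >= 0.4, (tt - 0.4)^2 * 10, 0)
  ths <- c(0.02, 0.05, 0.1, 0.5)
  onsets <- vapply(ths, function(th)
    detect_onset(pos, t = tt, threshold = th), numeric(1))
  expect_true(all(diff(onsets) >= 0))
})

test_that("blocker response requires motion in the attacker's direction", {
  dt <- 1 / 240
  tt <- (0:199) * dt
  # moves the wrong way first, then the right way
  v <- ifelse(tt < 0.4, -0.2, 0.3)
  pos <- cbind(cumsum(v) * dt, 0, 0)
  t_resp <- blocker_response(pos, direction = 1, t = tt, threshold = 0.05)
  expect_gte(t_resp, 0.4)
  # no movement: no response
  expect_true(is.na(blocker_response(matrix(0, 50, 3), direction = 1,
                                     dt = dt)))
  expect_error(blocker_response(pos, direction = 0, t = tt), "direction")
})
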