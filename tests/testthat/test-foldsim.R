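test_that("noiseless minimal fold relaxes to the stable root and stays", {
  cfg <- minimal_cfg(duration = 20)
  tr <- simulate_fold_minimal(cfg, y0 = -0.25, x0 = 0)
  # stable root of -0.25 + x^2 is -0.5; relaxation rate |f'| = 1 at the root
  tail_x <- tr$x[tr$t > 16]
  expect_true(all(abs(tail_x + 0.5) < 1e-6))
  expect_true(is.na(tr$escape_time))
})

test_that("minimal fold with positive slow value grows monotonically", {
  cfg <- minimal_cfg()
  tr <- simulate_fold_minimal(cfg, y0 = 0.1, x0 = 0)
  free <- tr$x[tr$x < cfg$x_bound]
  expect_true(all(diff(free) > 0))
  expect_false(is.na(tr$escape_time))
})

test_that("noiseless escape agrees with a fine-step integration oracle", {
  cfg <- minimal_cfg(epsilon = 0.01, duration = 20)
  tr <- simulate_fold_minimal(cfg, y0 = -0.05)
  lev <- 1
  t_pkg <- tr$t[which(tr$x >= lev)[1]]
  # independent forward-Euler oracle at a 50x finer step
  dtf <- cfg$dt / 50
  x <- -sqrt(0.05); y <- -0.05; tt <- 0; t_oracle <- NA
  while (tt < cfg$duration) {
    x <- x + dtf * (y + x^2); y <- y + dtf * 0.01; tt <- tt + dtf
    if (x >= lev) { t_oracle <- tt; break }
  }
  # first-order bias through the slow passage stays within a few readouts
  expect_lt(abs(t_pkg - t_oracle), 3 * cfg$dt)

  # halving dt moves the escape by at most one readout interval
  cfg2 <- minimal_cfg(epsilon = 0.01, duration = 20, dt = cfg$dt / 2)
  tr2 <- simulate_fold_minimal(cfg2, y0 = -0.05)
  t_half <- tr2$t[which(tr2$x >= lev)[1]]
  expect_lte(abs(t_pkg - t_half), cfg$dt + 1e-9)
})

test_that("dot-stimulus trajectory has the standard readout grid", {
  tr <- simulate_fold_exp3(exp3_cfg(seed = 4))
  expect_equal(length(tr$t), 151)  # 1.5 s inclusive at 10 ms readouts
  expect_equal(unique(round(diff(tr$t), 10)), 0.010)
  expect_true(tr$tstar_true >= 0.350 && tr$tstar_true <= 0.700)
  expect_true(tr$direction %in% c(-1L, 1L))
  expect_true(tr$detrended)
})

test_that("noiseless cubic model plateaus at the root of the cubic", {
  # passage through x ~ 0 at y = 0.01 takes ~ pi / sqrt(a y) ~ 16 s
  cfg <- sim_config(gamma = 0, epsilon = 0, duration = 25,
                    tstar_range = c(0, 25), seed = 1)
  tr <- simulate_fold(cfg, y0 = 0.01, x0 = 0)
  # oracle: positive root of 0.01 + 4 x^2 - x^3 = 0
  r <- polyroot(c(0.01, 0, 4, -1))
  root <- max(Re(r[abs(Im(r)) < 1e-8]))
  expect_equal(tr$x[length(tr$x)], root, tolerance = 1e-6)
  # y -> 0+ limit: plateau approaches a
  expect_equal(root, cfg$a, tolerance = 1e-2)
})

test_that("detrending zeroes a constant pre-transition signal", {
  cfg <- sim_config(gamma = 0, epsilon = 0, duration = 2,
                    tstar_range = c(0, 2), seed = 1)
  tr <- simulate_fold(cfg, y0 = -0.4)  # starts on the branch, stays there
  dtr <- detrend_trajectory(tr)
  expect_true(all(abs(dtr$x) < 1e-8))
})

test_that("detrending zeroes the quasi-static branch exactly", {
  cfg <- exp3_cfg()
  tstar <- 0.5
  tt <- seq(0, cfg$duration, by = cfg$dt)
  y <- cfg$epsilon * (tt - tstar)
  x <- ewsmotion:::stable_branch(y, cfg$a, cubic = TRUE)
  tr <- trajectory(tt, x, y, tstar_true = tstar, kind = "fold", cfg = cfg)
  dtr <- detrend_trajectory(tr)
  expect_true(all(abs(dtr$x[tt < tstar]) < 1e-9))
})

test_that("fold ensemble pre-transition mean is centered after detrending", {
  cfg <- exp3_cfg(seed = 7)
  ens <- generate_exp3_ensemble(cfg, n_per_arm = 100)
  pre <- unlist(lapply(ens$fold, function(tr) tr$x[tr$t < tr$tstar_true]))
  se <- stats::sd(pre) / sqrt(length(pre))
  # Monte-Carlo: overlapping noise makes samples correlated; 3 SE on the
  # naive count is conservative only up to that correlation, so allow 6.
  expect_lt(abs(mean(pre)), 6 * se)
})

test_that("noiseless step control is an exact Heaviside", {
  cfg <- exp3_cfg()
  tr <- simulate_heaviside_control(0.5, amplitude = 4, noise_amp = 0,
                                   cfg = cfg, seed = 3)
  x <- tr$direction * tr$x
  expect_true(all(x[tr$t < 0.5] == 0))
  expect_true(all(x[tr$t >= 0.5] == 4))
})

test_that("matched ensembles share transition times and reproduce exactly", {
  cfg <- exp3_cfg(seed = 11)
  ens1 <- generate_exp3_ensemble(cfg, n_per_arm = 20)
  ens2 <- generate_exp3_ensemble(cfg, n_per_arm = 20)
  expect_identical(ens1, ens2)
  t_fold <- vapply(ens1$fold, `[[`, numeric(1), "tstar_true")
  t_ctrl <- vapply(ens1$control, `[[`, numeric(1), "tstar_true")
  expect_identical(t_fold, t_ctrl)
  # control noise half-width matches the fold arm's pre-transition spread
  pre_sd <- mean(vapply(ens1$fold, function(tr)
    stats::sd(tr$x[tr$t < tr$tstar_true]), numeric(1)))
  expect_equal(ens1$noise_halfwidth, pre_sd * sqrt(3), tolerance = 1e-12)
})

test_that("pre-transition AR(1) of step controls is near the white-noise level", {
  cfg <- exp3_cfg(seed = 13)
  ens <- generate_exp3_ensemble(cfg, n_per_arm = 30)
  w <- window_spec(240, rate = 100)
  ar1 <- unlist(lapply(ens$control, function(tr) {
    s <- windowed_ar1(tr$x, w, t = tr$t)
    s$ar1[s$t < tr$tstar_true - 0.12]
  }))
  n <- w$n
  # i.i.d. windows: E[AR(1)-hat] ~ -1/(n-1); check within Monte-Carlo error
  expect_lt(abs(mean(ar1) + 1 / (n - 1)), 4 / sqrt(length(ar1) / n))
})

test_that("noiseless cubic trajectories stay bounded pre-escape", {
  cfg <- sim_config(gamma = 0, seed = 1)
  for (tstar in c(0.35, 0.5, 0.7)) {
    tr <- simulate_fold(cfg, y0 = -cfg$epsilon * tstar)
    pre <- tr$x[tr$t <= tr$tstar_true]
    expect_true(all(abs(pre) <= max(abs(tr$x[1]), cfg$a + 1)))
    expect_true(all(diff(tr$x[tr$t >= tr$tstar_true & tr$x < cfg$a]) >= 0))
  }
})

test_that("invalid simulator configurations are rejected", {
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(gamma = -1), "gamma")
  expect_error(sim_config(duration = 0.5, tstar_range = c(0.35, 0.7)),
               "duration")
  expect_error(simulate_fold_exp3(minimal_cfg()), "cubic")
  expect_error(simulate_heaviside_control(5, 4, 0.1, exp3_cfg()), "tstar")
})
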