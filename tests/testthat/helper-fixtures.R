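# Shared fixtures: small configurations used across test files.

# Minimal fold normal form (no cubic term), deterministic unless gamma set.
minimal_cfg <- function(gamma = 0, epsilon = 0, duration = 5, dt = 0.01) {
  sim_config(a = 1, gamma = gamma, epsilon = epsilon, dt = dt,
             duration = duration, tstar_range = c(0, duration),
             cubic = FALSE, seed = 1)
}

# Dot-stimulus configuration at the standard parameters.
exp3_cfg <- function(seed = 1, gamma = 0.063) {
  sim_config(gamma = gamma, seed = seed)
}

# Small, fast motion configuration (coarser but same structure).
motion_cfg <- function(seed = 1, ...) {
  motion_config(seed = seed, ...)
}

# Naive double-loop implementations of the windowed statistics, used as
# independent oracles against the package's implementations.
oracle_ar1 <- function(x) {
  v0 <- 0
  for (i in seq_along(x)) v0 <- v0 + x[i] / length(x)
  num <- 0; den <- 0
  for (i in seq_along(x)) den <- den + (x[i] - v0)^2
  for (i in 2:length(x)) num <- num + (x[i] - v0) * (x[i - 1] - v0)
  if (den == 0) NA_real_ else num / den
}

oracle_tau <- function(x, rate) {
  v0 <- mean(x)
  den <- 0
  for (i in seq_along(x)) den <- den + (x[i] - v0)^2
  if (den == 0) return(NA_real_)
  n <- length(x)
  for (l in 1:(n - 1)) {
    Rl <- 0
    for (i in (l + 1):n) Rl <- Rl + (x[i] - v0) * (x[i - l] - v0)
    if (Rl / den <= exp(-1)) return(l / rate * 1000)
  }
  NA_real_
}

oracle_var <- function(x) {
  v0 <- mean(x)
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - v0)^2
  s / (length(x) - 1)
}
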