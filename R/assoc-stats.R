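#' Density-based outlier filter for 2-D point clouds
#'
#' Estimates a smooth 2-D density of the points with a Gaussian product
#' kernel (normal-reference plug-in bandwidth, as in [MASS::kde2d()]) on
#' axis-standardized coordinates, and retains the points above the density
#' level whose super-level set contains approximately `coverage` of the
#' points. This removes low-density outliers -- e.g. false-positive
#' early-warning detections that make EWS times appear far earlier than the
#' motion they precede -- before regression. Standardizing the axes first
#' makes the mask invariant under affine rescaling of either axis.
#'
#' @param x,y Coordinates of the points.
#' @param coverage Target fraction of points to retain, in (0, 1]; 0.96,
#'   0.81 and 0.60 correspond to the inclusive/default/restrictive analysis
#'   levels.
#' @return Logical mask of retained points, with attributes
#'   `retained_fraction` and `degenerate` (TRUE when the cloud was
#'   degenerate and all points were kept).
#' @export
density_filter <- function(x, y, coverage = 0.81) {
  stopifnot("need >= 10 points" = length(x) >= 10,
            "x and y must have equal length" = length(x) == length(y),
            "coverage must be in (0, 1]" = coverage > 0 && coverage <= 1)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx < 1e-12 || sy < 1e-12) {
    mask <- rep(TRUE, length(x))
    attr(mask, "retained_fraction") <- 1
    attr(mask, "degenerate") <- TRUE
    return(mask)
  }
  zx <- (x - mean(x)) / sx
  zy <- (y - mean(y)) / sy
  hx <- MASS::bandwidth.nrd(zx) / 4
  hy <- MASS::bandwidth.nrd(zy) / 4
  if (hx <= 0 || hy <= 0) {
    mask <- rep(TRUE, length(x))
    attr(mask, "retained_fraction") <- 1
    attr(mask, "degenerate") <- TRUE
    return(mask)
  }
  dens <- vapply(seq_along(zx), function(i)
    mean(stats::dnorm(zx[i] - zx, sd = hx) *
         stats::dnorm(zy[i] - zy, sd = hy)), numeric(1))
  level <- stats::quantile(dens, probs = 1 - coverage, type = 7,
                           names = FALSE)
  mask <- dens >= level
  attr(mask, "retained_fraction") <- mean(mask)
  attr(mask, "degenerate") <- FALSE
  mask
}

#' Density-filtered regression of onset times on EWS times
#'
#' Ordinary least squares of motion-onset times on early-warning-signal
#' times over the density-retained points. When the slope is close to 1 the
#' intercept estimates the average lead time of the EWS over motion onset
#' (the quantity called delta-t); the mean difference over the retained
#' points is reported alongside as a robustness readout. Pairs with a
#' missing value in either coordinate are dropped first, and EWS times
#' earlier than `min_ews_time` (when given) are excluded as false positives
#' -- the rule used for Blocker analyses, where detections earlier than
#' 200 ms from trial start cannot reflect the Attacker's preparation.
#'
#' @param ews_times EWS detection times (s).
#' @param onset_times Matching motion-onset times (s).
#' @param coverage Density-filter coverage, see [density_filter()].
#' @param min_ews_time Exclude pairs with EWS time below this value (s), or
#'   `NULL` to keep all.
#' @return An object of class `delta_regression`: list with `slope`,
#'   `intercept`, `slope_se`, `intercept_se`, `mean_diff`, `mean_diff_se`,
#'   `retained_fraction`, `mask` (over the complete pairs entering the
#'   filter), `n_used`, `n_input`, `coverage_target`.
#' @export
delta_regression <- function(ews_times, onset_times, coverage = 0.81,
                             min_ews_time = NULL) {
  stopifnot(length(ews_times) == length(onset_times))
  ok <- is.finite(ews_times) & is.finite(onset_times)
  if (!is.null(min_ews_time)) ok <- ok & ews_times >= min_ews_time
  xs <- ews_times[ok]; ys <- onset_times[ok]
  if (length(xs) < 10) stop("fewer than 10 complete pairs to regress")
  mask <- density_filter(xs, ys, coverage)
  xr <- xs[mask]; yr <- ys[mask]
  if (length(xr) < 10) stop("fewer than 10 points retained by the filter")
  fit <- stats::lm(yr ~ xr)
  # exact synthetic inputs produce perfect fits; the summary warning about
  # them is expected there and carries no information
  sm <- suppressWarnings(summary(fit))$coefficients
  d <- yr - xr
  structure(list(slope = unname(sm["xr", "Estimate"]),
                 intercept = unname(sm["(Intercept)", "Estimate"]),
                 slope_se = unname(sm["xr", "Std. Error"]),
                 intercept_se = unname(sm["(Intercept)", "Std. Error"]),
                 mean_diff = mean(d),
                 mean_diff_se = stats::sd(d) / sqrt(length(d)),
                 retained_fraction = attr(mask, "retained_fraction"),
                 mask = as.logical(mask), n_used = length(xr),
                 n_input = length(ews_times),
                 coverage_target = coverage),
            class = "delta_regression")
}

#' @export
print.delta_regression <- function(x, ...) {
  cat(sprintf(
    "<delta_regression: slope %.3f (se %.3f), intercept %.4f (se %.4f), %d/%d pts>\n",
    x$slope, x$slope_se, x$intercept, x$intercept_se, x$n_used, x$n_input))
  invisible(x)
}

# Harrell-Davis quantile estimator: a smooth L-estimator weighting the order
# statistics by Beta((n+1)p, (n+1)(1-p)) increments.
hd_quantile <- function(x, p) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  vapply(p, function(pp) {
    i <- seq_len(n)
    w <- stats::pbeta(i / n, (n + 1) * pp, (n + 1) * (1 - pp)) -
      stats::pbeta((i - 1) / n, (n + 1) * pp, (n + 1) * (1 - pp))
    sum(w * x)
  }, numeric(1))
}

#' Compare two reaction-time distributions
#'
#' Two-sided Mann-Whitney rank-sum test with the rank-biserial effect size,
#' two-sample Kolmogorov-Smirnov test, and the shift function: the nine
#' decile differences (`rt_b` minus `rt_a`) using the Harrell-Davis quantile
#' estimator (the plain sample quantile is available as an alternative).
#' The shift function shows where along the distribution an effect acts: a
#' flat shift function indicates a uniform shift.
#'
#' @param rt_a,rt_b Reaction times of the two arms (same units, e.g. ms).
#' @param quantile_method `"hd"` (Harrell-Davis, default) or `"type7"`.
#' @return An object of class `rt_comparison`: list with `u_stat`, `p_mw`,
#'   `effect_size` (rank-biserial, positive when `rt_a` tends smaller),
#'   `ks_stat`, `p_ks`, `decile_diffs` (9 values), `n_a`, `n_b`,
#'   `ties_degenerate`.
#' @export
rt_compare <- function(rt_a, rt_b, quantile_method = c("hd", "type7")) {
  quantile_method <- match.arg(quantile_method)
  rt_a <- rt_a[is.finite(rt_a)]; rt_b <- rt_b[is.finite(rt_b)]
  stopifnot("each arm needs >= 5 values" =
              length(rt_a) >= 5 && length(rt_b) >= 5)
  degenerate <- length(unique(c(rt_a, rt_b))) == 1L
  if (degenerate) {
    u <- length(rt_a) * length(rt_b) / 2
    mw <- list(statistic = c(W = u), p.value = 1)
    ks <- list(statistic = c(D = 0), p.value = 1)
  } else {
    mw <- suppressWarnings(stats::wilcox.test(rt_a, rt_b, exact = FALSE,
                                              correct = TRUE))
    ks <- suppressWarnings(stats::ks.test(rt_a, rt_b))
  }
  u <- unname(mw$statistic)
  n1 <- length(rt_a); n2 <- length(rt_b)
  qf <- if (quantile_method == "hd") hd_quantile
        else function(x, p) stats::quantile(x, p, type = 7, names = FALSE)
  dec <- seq(0.1, 0.9, by = 0.1)
  structure(list(u_stat = u, p_mw = mw$p.value,
                 effect_size = 1 - 2 * u / (n1 * n2),
                 ks_stat = unname(ks$statistic), p_ks = ks$p.value,
                 decile_diffs = qf(rt_b, dec) - qf(rt_a, dec),
                 n_a = n1, n_b = n2, ties_degenerate = degenerate),
            class = "rt_comparison")
}

#' @export
print.rt_comparison <- function(x, ...) {
  cat(sprintf(
    "<rt_comparison: U=%.1f p=%.3g r=%.2f; KS D=%.3f p=%.3g; median shift %.1f>\n",
    x$u_stat, x$p_mw, x$effect_size, x$ks_stat, x$p_ks, x$decile_diffs[5]))
  invisible(x)
}
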