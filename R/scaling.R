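#' Extract the variance curve around the divergence point
#'
#' Finds the divergence point `T*` -- the first window-center time at which
#' the windowed variance exceeds `threshold` -- and returns the variance
#' curve on `[T* - span, T* + span]` (default 100 ms either side), with
#' times re-expressed relative to `T*` so curves from different trials can
#' be synchronized.
#'
#' @param var_series Data frame with columns `t` and `var` (e.g. from
#'   [windowed_variance()] or [ews_series()]).
#' @param threshold Divergence threshold in squared signal units.
#' @param span Half-width of the extracted curve, seconds.
#' @return A data frame with columns `t` (absolute), `rel_t` (relative to
#'   `T*`), and `var`, with attributes `tstar_cross` (the divergence time)
#'   and `truncated` (TRUE when the crossing sits too close to an edge for
#'   the full span); or `NULL` when the variance never crosses.
#' @export
extract_divergence_curve <- function(var_series, threshold, span = 0.100) {
  tcross <- detect_var_rise(var_series, threshold)
  if (is.na(tcross)) return(NULL)
  keep <- var_series$t >= tcross - span - 1e-9 &
          var_series$t <= tcross + span + 1e-9
  out <- data.frame(t = var_series$t[keep],
                    rel_t = var_series$t[keep] - tcross,
                    var = var_series$var[keep])
  dt <- stats::median(diff(var_series$t))
  attr(out, "tstar_cross") <- tcross
  attr(out, "truncated") <- (min(out$rel_t) > -span + dt / 2) ||
                            (max(out$rel_t) < span - dt / 2)
  out
}

#' Average divergence curves in blocks, synchronized on the divergence point
#'
#' Curves (from [extract_divergence_curve()]) are aligned on their relative
#' time axis, grouped into consecutive blocks of `block_size`, and averaged
#' pointwise within each block; block averaging suppresses the estimation
#' noise of the single-trial variance curves. Trials without a divergence
#' crossing (`NULL` curves) are excluded and counted.
#'
#' @param curves List of divergence curves (elements may be `NULL`).
#' @param block_size Number of curves per block; curves left over after the
#'   last full block form a final, smaller block.
#' @return A list of block-averaged curves (data frames with `rel_t`, `var`,
#'   and `n_curves`), with attribute `n_excluded`.
#' @export
average_block_curves <- function(curves, block_size = 30L) {
  excluded <- sum(vapply(curves, is.null, logical(1)))
  curves <- Filter(Negate(is.null), curves)
  if (length(curves) == 0) stop("no curves with a divergence crossing")
  blocks <- split(curves, (seq_along(curves) - 1L) %/% block_size)
  out <- lapply(blocks, function(bl) {
    grid <- sort(unique(round(unlist(lapply(bl, `[[`, "rel_t")), 9)))
    acc <- matrix(NA_real_, nrow = length(grid), ncol = length(bl))
    for (j in seq_along(bl)) {
      idx <- match(round(bl[[j]]$rel_t, 9), grid)
      acc[idx, j] <- bl[[j]]$var
    }
    data.frame(rel_t = grid,
               var = rowMeans(acc, na.rm = TRUE),
               n_curves = rowSums(!is.na(acc)))
  })
  names(out) <- NULL
  attr(out, "n_excluded") <- excluded
  out
}

#' Fit the power-law divergence model to a variance curve
#'
#' Fits \deqn{\log(\sigma^2) = -\log(b) + n \log(t^* - t)} by bounded
#' nonlinear least squares in log-variance space, over every sub-window of
#' `subwindow_ms` duration advanced by `offset_ms`, and returns the best fit
#' across sub-windows. The exponent `n` identifies the bifurcation type:
#' `-1/2` for a fold (saddle-node) transition versus `-1` for pitchfork/Hopf
#' transitions.
#'
#' "Best fit" is judged by the coefficient of determination in log space
#' (`criterion = "r2"`, the default): the selected sub-window is the one
#' where the power law explains the largest share of the curve's structure.
#' Selecting on raw residual sum of squares (`criterion = "sse"`) is
#' available for comparison but degenerates on curves with flat stretches,
#' where a near-constant sub-window attains a tiny SSE while containing no
#' divergence information.
#'
#' During optimization `t*` is bounded below by one sample interval beyond
#' the last time point of the sub-window, avoiding the log singularity;
#' three starting values of `t*` guard against local minima.
#'
#' @param curve Data frame with columns `rel_t` (or `t`) and `var`.
#' @param subwindow_ms Sub-window duration in ms (default 48).
#' @param offset_ms Sub-window advance in ms (default 4).
#' @param criterion Sub-window selection rule: `"r2"` (default) or `"sse"`.
#' @param anchor `"none"` (default): fit every sub-window position and select
#'   by `criterion`; `"end"`: fit only the sub-window that ends at the last
#'   point of the curve. The anchored variant is appropriate for coarsely
#'   sampled curves (few points per sub-window), where selection among
#'   overfitted 3-parameter sub-window fits is noise-dominated and the
#'   divergence information is concentrated immediately before the
#'   synchronization point.
#' @return An object of class `powerlaw_fit`: list with `b`, `n`,
#'   `tstar_fit`, `sse`, `sse_per_point`, `r_squared`, `window_index`,
#'   `window_rel_t`, `n_points`, `converged`.
#' @export
fit_powerlaw <- function(curve, subwindow_ms = 48, offset_ms = 4,
                         criterion = c("r2", "sse"),
                         anchor = c("none", "end")) {
  criterion <- match.arg(criterion)
  anchor <- match.arg(anchor)
  tcol <- if ("rel_t" %in% names(curve)) "rel_t" else "t"
  tt <- curve[[tcol]]
  vv <- curve$var
  ok <- is.finite(tt) & is.finite(vv) & vv > 0
  tt <- tt[ok]; vv <- vv[ok]
  if (length(tt) < 4) stop("too few valid points to fit the power law")
  dt <- stats::median(diff(tt))
  sub_len <- subwindow_ms / 1000
  if (anchor == "end") {
    nsub <- max(4L, as.integer(floor(sub_len / dt + 1e-9)) + 1L)
    starts <- max(1L, length(tt) - nsub + 1L)
  } else {
    starts <- unique(vapply(
      seq(tt[1], max(tt[1], tt[length(tt)] - sub_len), by = offset_ms / 1000),
      function(s) which.min(abs(tt - s)), integer(1)))
  }
  best <- NULL
  better <- function(fit, best) {
    if (is.null(best)) return(TRUE)
    if (criterion == "r2") fit$r_squared > best$r_squared
    else fit$sse_per_point < best$sse_per_point
  }
  for (wi in seq_along(starts)) {
    i0 <- starts[wi]
    i1 <- max(which(tt <= tt[i0] + sub_len + 1e-9))
    if (i1 - i0 + 1L < 4L) next
    ts <- tt[i0:i1]; vs <- vv[i0:i1]
    fit <- fit_powerlaw_window(ts, log(vs), dt)
    if (is.null(fit)) next
    if (better(fit, best)) {
      best <- fit
      best$window_index <- wi
      best$window_rel_t <- c(ts[1], ts[length(ts)])
    }
  }
  if (is.null(best)) stop("power-law fit failed to converge in every sub-window")
  class(best) <- "powerlaw_fit"
  best
}

# Single-window bounded Levenberg-Marquardt fit of the log-space model,
# multi-started over three t* initializations.
fit_powerlaw_window <- function(ts, lv, dt) {
  t_end <- ts[length(ts)]
  lower <- c(lb = -60, n = -30, tstar = t_end + dt)
  upper <- c(lb = 60, n = 30, tstar = t_end + 10)
  best <- NULL
  for (t0 in t_end + c(0.010, 0.030, 0.080)) {
    # model: lv = -lb + n*log(tstar - t); init lb consistent with curve end
    n0 <- -0.5
    lb0 <- -lv[length(lv)] + n0 * log(t0 - t_end + dt)
    lb0 <- min(max(lb0, lower[1]), upper[1])
    st <- list(lb = lb0, n = n0, tstar = max(t0, lower[3] + dt / 2))
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        lv ~ -lb + n * log(tstar - ts),
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) {
      cf <- stats::coef(fit)
      sstot <- sum((lv - mean(lv))^2)
      best <- list(b = exp(unname(cf["lb"])), n = unname(cf["n"]),
                   tstar_fit = unname(cf["tstar"]), sse = sse,
                   sse_per_point = sse / length(lv),
                   r_squared = if (sstot > 0) 1 - sse / sstot else 0,
                   n_points = length(lv), converged = TRUE)
    }
  }
  best
}

#' Median divergence exponent across fitted curves
#'
#' Applies [fit_powerlaw()] to each block-averaged curve and returns the
#' median exponent over fits with `|n| < n_max` (default 1.5, the truncation
#' used when summarizing the exponent histogram).
#'
#' @param curves List of curves (e.g. from [average_block_curves()]).
#' @param subwindow_ms,offset_ms,criterion,anchor Passed to [fit_powerlaw()].
#' @param n_max Exponent-magnitude truncation for the summary.
#' @return List with `median_n`, `n_values` (all fitted exponents),
#'   `n_kept`, `n_failed`.
#' @export
median_divergence_exponent <- function(curves, subwindow_ms = 48,
                                       offset_ms = 4, n_max = 1.5,
                                       criterion = "r2", anchor = "none") {
  fits <- lapply(curves, function(cu)
    tryCatch(fit_powerlaw(cu, subwindow_ms, offset_ms,
                          criterion = criterion, anchor = anchor),
             error = function(e) NULL))
  nvals <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$n,
                  numeric(1))
  kept <- nvals[!is.na(nvals) & abs(nvals) < n_max]
  list(median_n = stats::median(kept), n_values = nvals,
       n_kept = length(kept), n_failed = sum(is.na(nvals)))
}
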