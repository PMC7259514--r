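#' First principal component of multi-sensor body motion
#'
#' Pools the 3-D position columns of all body sensors (finger excluded by
#' default), centers them, and extracts the first principal component of the
#' pooled sensor-coordinate matrix. The projection of each time sample onto
#' the first PC gives a single body-motion series; when all sensors share a
#' common motion component the first PC acts as a center-of-mass coordinate
#' and the loadings are spread evenly across sensors. Loadings are reported
#' as squared-loading percentages per sensor coordinate (summing to 100).
#'
#' The projection sign is fixed toward the reach direction: the component is
#' oriented so that its net displacement (last minus first sample) is
#' positive, and the stored trial direction, when present, is used to express
#' the projection in reach-ward units.
#'
#' @param trial A `sensor_trial` (see [generate_attacker_trial()]) or a named
#'   list of T x 3 position matrices.
#' @param exclude Character vector of sensor names to exclude.
#' @return List with `loadings` (named vector over sensor coordinates),
#'   `loadings_pct` (squared-loading percent), `sensor_pct` (percent summed
#'   per sensor), `projection` (length-T series), and `fallback` (TRUE when
#'   the input was degenerate and the center of mass was used instead).
#' @export
first_pc <- function(trial, exclude = "finger") {
  pos <- if (inherits(trial, "sensor_trial")) trial$pos else trial
  keep <- setdiff(names(pos), exclude)
  if (length(keep) < 2) stop("need at least 2 sensors after exclusion")
  mat <- do.call(cbind, lapply(keep, function(s) pos[[s]]))
  colnames(mat) <- paste(rep(keep, each = 3), c("x", "y", "z"), sep = ".")
  cmat <- scale(mat, center = TRUE, scale = FALSE)
  sds <- apply(cmat, 2, stats::sd)
  if (all(sds < 1e-12)) {
    com <- center_of_mass_matrix(pos, keep)
    return(list(loadings = NULL, loadings_pct = NULL, sensor_pct = NULL,
                projection = com[, 1] - mean(com[, 1]), fallback = TRUE))
  }
  pc <- stats::prcomp(cmat, center = FALSE, scale. = FALSE)
  load1 <- pc$rotation[, 1]
  proj <- pc$x[, 1]
  if (proj[length(proj)] - proj[1] < 0) {
    proj <- -proj
    load1 <- -load1
  }
  pct <- 100 * load1^2 / sum(load1^2)
  sensor_pct <- tapply(pct, rep(keep, each = 3), sum)[keep]
  list(loadings = load1, loadings_pct = pct,
       sensor_pct = sensor_pct, projection = proj, fallback = FALSE)
}

center_of_mass_matrix <- function(pos, keep) {
  Reduce(`+`, pos[keep]) / length(keep)
}

#' Center of mass of the body sensors
#'
#' Unweighted mean 3-D position across the body sensors at every sample.
#'
#' @inheritParams first_pc
#' @return A T x 3 matrix.
#' @export
center_of_mass <- function(trial, exclude = "finger") {
  pos <- if (inherits(trial, "sensor_trial")) trial$pos else trial
  keep <- setdiff(names(pos), exclude)
  if (length(keep) < 1) stop("need at least 1 body sensor")
  center_of_mass_matrix(pos, keep)
}

#' Detect motion onset by a speed threshold
#'
#' Motion onset is the first time the speed -- the Euclidean norm of the
#' first-difference velocity -- exceeds `threshold` (default 0.05 cm/s). The
#' velocity at sample `i` is `(p_i - p_{i-1}) / dt`, timestamped at `t_i`, so
#' a ramp starting at `t0` is detected at `t0` plus one sample.
#'
#' @param series Position series: a T x d matrix or a numeric vector (cm).
#' @param t Sample times (s), or `NULL` to use `dt`-spaced times from 0.
#' @param dt Sample interval (s), required when `t` is `NULL`.
#' @param threshold Speed threshold in cm/s.
#' @return Onset time in seconds, or `NA_real_` if the speed never crosses.
#' @export
detect_onset <- function(series, t = NULL, dt = NULL, threshold = 0.05) {
  m <- as.matrix(series)
  if (nrow(m) < 2) stop("need at least 2 samples")
  if (is.null(t)) {
    stopifnot("supply t or dt" = !is.null(dt))
    t <- (seq_len(nrow(m)) - 1L) * dt
  }
  dtv <- diff(t)
  v <- diff(m) / dtv
  speed <- sqrt(rowSums(v^2))
  idx <- which(speed > threshold)
  if (length(idx) == 0) NA_real_ else t[idx[1] + 1L]
}

#' Detect the Blocker's directional response
#'
#' The Blocker's response time is the first time the signed velocity along
#' the target axis exceeds the speed threshold in the same direction as the
#' Attacker's motion.
#'
#' @param series Blocker finger position: T x d matrix (target axis first
#'   column) or numeric vector.
#' @param direction +1 or -1, the Attacker's motion direction.
#' @param axis Column index of the target axis.
#' @inheritParams detect_onset
#' @return Response time in seconds, or `NA_real_`.
#' @export
blocker_response <- function(series, direction, t = NULL, dt = NULL,
                             threshold = 0.05, axis = 1L) {
  stopifnot("direction must be +1 or -1" = direction %in% c(-1, 1))
  m <- as.matrix(series)
  if (nrow(m) < 2) stop("need at least 2 samples")
  if (is.null(t)) {
    stopifnot("supply t or dt" = !is.null(dt))
    t <- (seq_len(nrow(m)) - 1L) * dt
  }
  v <- diff(m[, axis]) / diff(t)
  idx <- which(direction * v > threshold)
  if (length(idx) == 0) NA_real_ else t[idx[1] + 1L]
}
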