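#' Write a trajectory to delimited text
#'
#' Tab-separated columns `time_s`, `x` (and `y` when present), preceded by
#' `#`-comment header lines carrying the JSON-encoded metadata (model
#' configuration, seed, true transition time, direction, kind), so a file is
#' self-describing and round-trips through [read_trajectory()].
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  meta <- list(cfg = unclass(traj$cfg), seed = traj$seed,
               tstar_true = traj$tstar_true, direction = traj$direction,
               kind = traj$kind, escape_time = traj$escape_time,
               detrended = traj$detrended)
  hdr <- paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                       null = "null"))
  df <- data.frame(time_s = traj$t, x = traj$x)
  if (!is.null(traj$y)) df$y <- traj$y
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path File path.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  meta <- jsonlite::fromJSON(sub("^# ", "", hdr[1]))
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t")
  cfg <- meta$cfg
  if (!is.null(cfg)) class(cfg) <- "sim_config"
  trajectory(df$time_s, df$x, y = df$y, tstar_true = meta$tstar_true,
             direction = meta$direction, kind = meta$kind, cfg = cfg,
             seed = meta$seed,
             escape_time = if (is.null(meta$escape_time)) NA_real_
                           else meta$escape_time,
             detrended = isTRUE(meta$detrended))
}

#' Write a sensor trial to delimited text with a JSON sidecar
#'
#' One row per sample: `time_s` followed by `x/y/z` columns per sensor
#' (body sensors, `finger`, `blocker_finger`). Ground truth and the
#' generator configuration go to `<path>.json`.
#'
#' @param trial A `sensor_trial`.
#' @param path Output file path for the table; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_sensor_trial <- function(trial, path) {
  chans <- c(trial$pos, list(blocker_finger = trial$blocker_finger))
  df <- data.frame(time_s = trial$t)
  for (nm in names(chans)) {
    m <- chans[[nm]]
    colnames(m) <- paste(nm, c("x", "y", "z"), sep = ".")
    df <- cbind(df, m)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(truth = trial$truth,
                            cfg = unclass(trial$cfg), seed = trial$seed),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a sensor trial written by [write_sensor_trial()]
#'
#' @param path Table file path (sidecar `<path>.json` must exist).
#' @return A `sensor_trial`.
#' @export
read_sensor_trial <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  nm <- unique(sub("\\.[xyz]$", "", setdiff(names(df), "time_s")))
  chans <- lapply(nm, function(s) {
    m <- as.matrix(df[, paste(s, c("x", "y", "z"), sep = ".")])
    colnames(m) <- c("x", "y", "z")
    m
  })
  names(chans) <- nm
  cfg <- meta$cfg
  if (!is.null(cfg)) class(cfg) <- "motion_config"
  structure(list(t = df$time_s,
                 pos = chans[setdiff(nm, "blocker_finger")],
                 blocker_finger = chans$blocker_finger,
                 truth = meta$truth, cfg = cfg, seed = meta$seed),
            class = "sensor_trial")
}
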