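#' Marker trial container
#'
#' A `gait_trial` bundles synchronized 3D marker trajectories sampled on a
#' uniform time grid with the trial metadata needed downstream (side of
#' paresis, treadmill speed, protocol period labels). Positions are stored
#' in meters in a lab frame where `x` is mediolateral (+x toward the
#' participant's right), `y` is anteroposterior (+y anterior; the belt
#' surface moves in -y), and `z` is vertical (up).
#'
#' @param data Tibble or data frame with a `time` column (seconds) and one
#'   `<marker>_<x|y|z>` column triplet per marker.
#' @param rate_hz Sampling rate in samples per second.
#' @param meta Named list. Recognized entries: `paretic_side` (`"left"` or
#'   `"right"`), `treadmill_speed_mps`, `period_labels` (data frame with
#'   `start_s`, `end_s`, `label`).
#' @param max_gap_s Maximum duration of a missing-data run that is repaired
#'   by linear interpolation; longer gaps are a fatal error.
#' @param require_markers Markers that must be present.
#'
#' @return An object of class `gait_trial`: a list with elements `data`
#'   (tibble), `rate_hz`, `meta`, and `filtered` (logical).
#' @export
gait_trial <- function(data, rate_hz, meta = list(),
                       max_gap_s = 0.1,
                       require_markers = c("sacrum", "heel_left", "heel_right")) {
  data <- as_tibble(data)
  if (!"time" %in% names(data)) abort("`data` must contain a `time` column.")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    abort("`rate_hz` must be a positive scalar.")
  }
  mk <- trial_marker_names(data)
  missing_mk <- setdiff(require_markers, mk)
  if (length(missing_mk) > 0L) {
    abort(paste0("Required marker(s) missing from trial data: ",
                 paste(missing_mk, collapse = ", ")))
  }
  tt <- data$time
  n <- length(tt)
  if (n < 3L) abort("Trial must contain at least 3 frames.")
  dt <- diff(tt)
  if (any(dt <= 0)) abort("`time` must be strictly increasing.")
  if (max(abs(dt - 1 / rate_hz)) > 1e-9) {
    abort(sprintf(
      "Non-uniform time grid: max deviation from 1/rate is %.3g s (tolerance 1e-9 s).",
      max(abs(dt - 1 / rate_hz))))
  }
  pos_cols <- setdiff(names(data), "time")
  for (cl in pos_cols) {
    data[[cl]] <- repair_gaps(data[[cl]], rate_hz, max_gap_s, cl)
  }
  if (!all(vapply(data[pos_cols], function(v) all(is.finite(v)), logical(1)))) {
    abort("Non-finite positions remain after gap handling.")
  }
  if (!is.null(meta$paretic_side) &&
      !meta$paretic_side %in% c("left", "right")) {
    abort("`meta$paretic_side` must be \"left\" or \"right\".")
  }
  structure(
    list(data = data, rate_hz = rate_hz, meta = meta, filtered = FALSE),
    class = "gait_trial"
  )
}

trial_marker_names <- function(data) {
  cols <- grep("_(x|y|z)$", setdiff(names(data), "time"), value = TRUE)
  unique(sub("_(x|y|z)$", "", cols))
}

#' Marker names present in a trial
#' @param trial A `gait_trial`.
#' @return Character vector of marker names.
#' @export
markers <- function(trial) {
  stopifnot(inherits(trial, "gait_trial"))
  trial_marker_names(trial$data)
}

# Linear interpolation of interior NA runs no longer than max_gap_s.
repair_gaps <- function(x, rate_hz, max_gap_s, colname) {
  if (!anyNA(x)) return(x)
  na <- is.na(x)
  if (na[1L] || na[length(x)]) {
    abort(sprintf("Column `%s` starts or ends with missing data; cannot interpolate.", colname))
  }
  r <- rle(na)
  run_len <- r$lengths[r$values]
  if (any(run_len / rate_hz > max_gap_s)) {
    abort(sprintf(
      "Column `%s` has a gap of %.3f s, longer than the %.3f s repair limit.",
      colname, max(run_len) / rate_hz, max_gap_s))
  }
  idx <- seq_along(x)
  approx(idx[!na], x[!na], xout = idx)$y
}

#' @export
print.gait_trial <- function(x, ...) {
  dur <- x$data$time[nrow(x$data)] - x$data$time[1L]
  cat(sprintf("<gait_trial> %d frames @ %g Hz (%.1f s), markers: %s\n",
              nrow(x$data), x$rate_hz, dur,
              paste(markers(x), collapse = ", ")))
  if (!is.null(x$meta$paretic_side)) {
    cat(sprintf("  paretic side: %s; treadmill speed: %s m/s\n",
                x$meta$paretic_side,
                x$meta$treadmill_speed_mps %||% "?"))
  }
  cat(sprintf("  low-pass filtered: %s\n", x$filtered))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a marker trial from disk
#'
#' Reads a wide CSV (`time, sacrum_x, sacrum_y, sacrum_z, heel_left_x, ...`,
#' SI units) or a TRC motion-capture file. TRC positions are converted to
#' meters using the units declared in the TRC header, and the TRC X/Y/Z
#' axes are taken as mediolateral/anteroposterior/vertical.
#'
#' @param path File path.
#' @param format `"csv"` or `"trc"`.
#' @param meta Trial metadata list (see [gait_trial()]).
#' @param ... Passed to [gait_trial()].
#' @return A [gait_trial()].
#' @export
read_trial <- function(path, format = c("csv", "trc"), meta = list(), ...) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "csv") {
    data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    dt <- stats::median(diff(data$time))
    rate <- round(1 / dt)
    gait_trial(data, rate_hz = rate, meta = meta, ...)
  } else {
    read_trc(path, meta = meta, ...)
  }
}

read_trc <- function(path, meta = list(), ...) {
  lines <- readLines(path)
  if (length(lines) < 6L) abort("TRC file too short to contain a header and data.")
  hdr_keys <- strsplit(lines[2L], "\t")[[1L]]
  hdr_vals <- strsplit(lines[3L], "\t")[[1L]]
  hdr <- setNames(as.list(hdr_vals), hdr_keys)
  rate <- as.numeric(hdr[["DataRate"]])
  units <- hdr[["Units"]]
  scale <- switch(units, mm = 1e-3, cm = 1e-2, m = 1, abort(
    paste0("Unsupported TRC units: ", units)))
  marker_row <- strsplit(lines[4L], "\t")[[1L]]
  mk <- marker_row[-(1:2)]
  mk <- mk[nzchar(mk)]
  body <- lines[-(1:5)]
  body <- body[nzchar(trimws(body))]
  mat <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  if (ncol(mat) != 2L + 3L * length(mk)) {
    abort(sprintf("TRC data has %d columns; expected %d for %d markers.",
                  ncol(mat), 2L + 3L * length(mk), length(mk)))
  }
  # TRC time stamps are printed at limited precision; snap them to the
  # DataRate grid when they agree with it to within a millisecond.
  tt <- mat[, 2L]
  grid <- (seq_along(tt) - 1L) / rate + tt[1L]
  if (max(abs(tt - grid)) < 1e-3) tt <- grid
  data <- tibble(time = tt)
  for (i in seq_along(mk)) {
    base <- 2L + 3L * (i - 1L)
    data[[paste0(mk[i], "_x")]] <- mat[, base + 1L] * scale
    data[[paste0(mk[i], "_y")]] <- mat[, base + 2L] * scale
    data[[paste0(mk[i], "_z")]] <- mat[, base + 3L] * scale
  }
  gait_trial(data, rate_hz = rate, meta = meta, ...)
}

#' Write a marker trial to a wide CSV
#'
#' Inverse of [read_trial()] for the CSV dialect; positions in meters.
#'
#' @param trial A `gait_trial`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "gait_trial"))
  readr::write_csv(trial$data, path)
  invisible(path)
}

#' Zero-phase low-pass filter of all marker channels
#'
#' Applies a 4th-order Butterworth filter forward and backward (zero net
#' phase shift) to every position channel. Edge effects are controlled by
#' odd-reflection padding before filtering, so constant channels pass
#' through unchanged.
#'
#' @param trial A `gait_trial`.
#' @param cutoff_hz Cutoff frequency; must be below the Nyquist frequency.
#' @return The filtered `gait_trial` (metadata preserved, `filtered = TRUE`).
#' @export
lowpass_trial <- function(trial, cutoff_hz = 10) {
  stopifnot(inherits(trial, "gait_trial"))
  out <- trial
  pos_cols <- setdiff(names(trial$data), "time")
  for (cl in pos_cols) {
    out$data[[cl]] <- lowpass_series(trial$data[[cl]], trial$rate_hz, cutoff_hz)
  }
  out$filtered <- TRUE
  out
}

#' Zero-phase low-pass filter of a numeric series
#'
#' The filtering primitive behind [lowpass_trial()], exposed so that
#' derived series (e.g. velocities) can be filtered identically.
#'
#' @param x Numeric series on a uniform grid.
#' @param rate_hz Sampling rate of `x`.
#' @param cutoff_hz Cutoff frequency (must satisfy `rate_hz > 2 * cutoff_hz`).
#' @return Filtered series, same length as `x`.
#' @export
lowpass_series <- function(x, rate_hz, cutoff_hz = 10) {
  if (cutoff_hz >= rate_hz / 2) {
    abort(sprintf("Cutoff (%g Hz) must be below the Nyquist frequency (%g Hz).",
                  cutoff_hz, rate_hz / 2))
  }
  n <- length(x)
  bf <- signal::butter(4, cutoff_hz / (rate_hz / 2))
  pad <- min(n - 1L, as.integer(ceiling(rate_hz)))
  head_pad <- 2 * x[1L] - x[(pad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(pad + 1L):(pad + n)]
}

#' Finite-difference velocity of one marker axis
#'
#' Central differences on the uniform grid, one-sided at the endpoints,
#' giving a series the same length as the trial.
#'
#' @param trial A `gait_trial` (normally low-pass filtered first).
#' @param marker Marker name, e.g. `"heel_left"`.
#' @param axis `"ml"`, `"ap"`, or `"vertical"`.
#' @return Numeric vector of velocities (m/s) aligned with `trial$data$time`.
#' @export
marker_velocity <- function(trial, marker, axis = c("ap", "ml", "vertical")) {
  stopifnot(inherits(trial, "gait_trial"))
  axis <- match.arg(axis)
  suffix <- c(ml = "x", ap = "y", vertical = "z")[[axis]]
  col <- paste0(marker, "_", suffix)
  if (!col %in% names(trial$data)) {
    abort(paste0("Unknown marker/axis combination: ", marker, " / ", axis))
  }
  diff_series(trial$data[[col]], trial$rate_hz)
}

# Central differences, one-sided at endpoints; second-order accurate inside.
diff_series <- function(x, rate_hz) {
  n <- length(x)
  v <- numeric(n)
  v[1L] <- (x[2L] - x[1L]) * rate_hz
  v[n] <- (x[n] - x[n - 1L]) * rate_hz
  v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * rate_hz / 2
  v
}
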