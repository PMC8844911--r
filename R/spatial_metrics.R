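#' Per-step spatial metrics and pelvis state
#'
#' All mediolateral quantities share one signed convention, applied per
#' step: positive is the direction from the stance heel toward the
#' swing-leg side (+x lab for right steps, -x lab for left steps). Under
#' this convention "a wider step when the pelvis is displaced farther or
#' moving faster away from the stance foot" is a positive-coefficient
#' relationship on both sides, and crossover steps get negative widths.
#'
#' @name spatial_metrics
NULL

# +1 when the swinging foot is the right, -1 when it is the left.
swing_sign <- function(foot) ifelse(foot == "right", 1, -1)

ml_col <- function(marker) paste0(marker, "_x")
ap_col <- function(marker) paste0(marker, "_y")

#' Signed step width
#'
#' Mediolateral displacement between the placing (ipsilateral) heel at the
#' step end and the stance (contralateral) heel at the step start, signed
#' so that normal (non-crossover) steps are positive.
#'
#' @param trial A filtered `gait_trial`.
#' @param steps A `step_table` (one or more rows).
#' @return Numeric vector of widths in meters, one per step.
#' @export
step_width <- function(trial, steps) {
  d <- trial$data
  ipsi <- paste0("heel_", steps$foot)
  contra <- steps$stance_heel
  ml_end <- mapply(function(m, i) d[[ml_col(m)]][i], ipsi, steps$end_index)
  ml_start <- mapply(function(m, i) d[[ml_col(m)]][i], contra, steps$start_index)
  unname(swing_sign(steps$foot) * (ml_end - ml_start))
}

#' Step length on a treadmill
#'
#' Difference between the anterior position of the placing heel at this
#' step's end and that of the contralateral heel at the previous step's
#' end, plus the belt travel `v_belt * (t_end - t_prev_end)` (the belt
#' carries stance feet posteriorly). Undefined (`NA`) for the first step.
#'
#' @inheritParams step_width
#' @param treadmill_speed_mps Belt speed; defaults to the trial metadata.
#' @return Numeric vector of step lengths in meters (`NA` for step 1).
#' @export
step_length <- function(trial, steps, treadmill_speed_mps = NULL) {
  v_belt <- treadmill_speed_mps %||% trial$meta$treadmill_speed_mps
  if (is.null(v_belt)) abort("Treadmill speed not given and absent from trial meta.")
  d <- trial$data
  n <- nrow(steps)
  out <- rep(NA_real_, n)
  if (n < 2L) return(out)
  for (i in 2:n) {
    ipsi <- paste0("heel_", steps$foot[i])
    contra <- steps$stance_heel[i]
    y_end <- d[[ap_col(ipsi)]][steps$end_index[i]]
    y_prev <- d[[ap_col(contra)]][steps$end_index[i - 1L]]
    out[i] <- y_end - y_prev +
      v_belt * (steps$end_time_s[i] - steps$end_time_s[i - 1L])
  }
  out
}

#' Signed mediolateral foot placement
#'
#' Mediolateral displacement between the sacrum and the placing heel at
#' the step end, positive when the heel lands lateral to the sacrum on the
#' swing side (side-symmetric sign convention).
#'
#' @inheritParams step_width
#' @return Numeric vector in meters.
#' @export
foot_placement <- function(trial, steps) {
  d <- trial$data
  ipsi <- paste0("heel_", steps$foot)
  heel_ml <- mapply(function(m, i) d[[ml_col(m)]][i], ipsi, steps$end_index)
  sac_ml <- d$sacrum_x[steps$end_index]
  unname(swing_sign(steps$foot) * (heel_ml - sac_ml))
}

#' Pelvis displacement and velocity over normalized step time
#'
#' Samples the signed mediolateral displacement of the sacrum relative to
#' the (instantaneous) stance-heel position, and the signed sacrum ML
#' velocity, at 101 normalized time points `0..100` spanning the step.
#' Values between frames come from linear interpolation of the filtered
#' trajectories. The sample at point 0 is the `x_pelvis` the force-field
#' controller uses for that step.
#'
#' @param trial A filtered `gait_trial`.
#' @param step A single-row `step_table` slice.
#' @param n_points Number of normalized time points (default 101).
#' @return List with numeric vectors `disp` (m) and `vel` (m/s), each of
#'   length `n_points`.
#' @export
pelvis_state_curve <- function(trial, step, n_points = 101L) {
  stopifnot(nrow(step) == 1L)
  d <- trial$data
  tt <- d$time
  ts <- step$start_time_s + seq(0, 1, length.out = n_points) *
    (step$end_time_s - step$start_time_s)
  sgn <- swing_sign(step$foot)
  sac <- approx(tt, d$sacrum_x, xout = ts)$y
  stance <- approx(tt, d[[ml_col(step$stance_heel)]], xout = ts)$y
  sac_vel <- approx(tt, diff_series(d$sacrum_x, trial$rate_hz), xout = ts)$y
  list(disp = sgn * (sac - stance), vel = sgn * sac_vel)
}

#' Compute the full per-step metrics table
#'
#' One row per retained step: signed step width, step length, signed foot
#' placement, minute index (half-open minutes keyed by the step's end
#' time), and the pelvis displacement/velocity curves over normalized step
#' time as list columns.
#'
#' @param trial A filtered `gait_trial`.
#' @param steps A `step_table` from [segment_steps()]; segmented on demand
#'   when omitted.
#' @param treadmill_speed_mps Belt speed override (defaults to trial meta).
#' @param n_points Normalized time points per step (default 101).
#' @return Tibble (class `step_metrics`) with columns `step`, `side`,
#'   `foot`, `start_time_s`, `end_time_s`, `minute_index`, `step_width_m`,
#'   `step_length_m`, `foot_placement_m`, `pelvis_disp_m`, `pelvis_vel_mps`.
#' @export
step_metrics <- function(trial, steps = NULL, treadmill_speed_mps = NULL,
                         n_points = 101L) {
  if (is.null(steps)) steps <- segment_steps(trial)
  curves <- lapply(seq_len(nrow(steps)), function(i) {
    pelvis_state_curve(trial, steps[i, ], n_points = n_points)
  })
  out <- steps |>
    as_tibble() |>
    mutate(
      minute_index = minute_of(.data$end_time_s),
      step_width_m = step_width(trial, steps),
      step_length_m = step_length(trial, steps, treadmill_speed_mps),
      foot_placement_m = foot_placement(trial, steps),
      pelvis_disp_m = lapply(curves, `[[`, "disp"),
      pelvis_vel_mps = lapply(curves, `[[`, "vel")
    ) |>
    select("step", "side", "foot", "start_time_s", "end_time_s",
           "minute_index", "step_width_m", "step_length_m",
           "foot_placement_m", "pelvis_disp_m", "pelvis_vel_mps")
  class(out) <- c("step_metrics", class(out))
  attr(out, "qc") <- attr(steps, "qc")
  out
}
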