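#' Detect swing onsets from a heel anteroposterior velocity series
#'
#' On a treadmill, a heel moves posteriorly with the belt during stance and
#' anteriorly during swing, so a swing onset is the instant the heel's AP
#' velocity crosses from posterior (negative) to anterior (non-negative).
#' Low-pass filtering leaves micro-oscillations near zero, so a crossing is
#' only accepted if the velocity stays non-negative for a debounce interval
#' and if the previous accepted onset on the same heel is at least a
#' refractory interval earlier.
#'
#' @param ap_velocity Heel AP velocity series (m/s) from a filtered trial.
#' @param rate_hz Sampling rate of the series.
#' @param debounce_s Minimum time the velocity must remain `>= 0` after a
#'   crossing for it to count (default 0.05 s).
#' @param refractory_s Minimum spacing between accepted onsets on the same
#'   heel (default 0.2 s).
#' @return Sorted integer vector of sample indices (1-based), possibly empty.
#' @export
detect_swing_onsets <- function(ap_velocity, rate_hz,
                                debounce_s = 0.05, refractory_s = 0.2) {
  n <- length(ap_velocity)
  if (n < 2L) return(integer(0))
  nonneg <- ap_velocity >= 0
  cross <- which(!nonneg[-n] & nonneg[-1L]) + 1L
  if (length(cross) == 0L) return(integer(0))
  hold <- max(1L, as.integer(round(debounce_s * rate_hz)))
  keep <- vapply(cross, function(i) {
    j <- min(n, i + hold - 1L)
    all(nonneg[i:j])
  }, logical(1))
  cross <- cross[keep]
  if (length(cross) <= 1L) return(cross)
  refr <- refractory_s * rate_hz
  out <- cross[1L]
  for (i in cross[-1L]) {
    if (i - out[length(out)] >= refr) out <- c(out, i)
  }
  out
}

#' Segment a trial into steps
#'
#' A step starts at a swing onset of the ipsilateral heel and ends at the
#' next swing onset of the contralateral heel (the shared event that starts
#' the following step). Steps are labeled `paretic`/`nonparetic` using
#' `trial$meta$paretic_side`. Candidates that are implausibly short or
#' long, or onsets not followed by a contralateral onset, are dropped and
#' recorded in the QC attribute.
#'
#' @param trial A filtered `gait_trial` whose metadata names the paretic side.
#' @param min_step_s,max_step_s Plausible step duration bounds.
#' @param ... Passed to [detect_swing_onsets()].
#' @return A tibble of steps (class `step_table`) with columns `step`,
#'   `side` (`"paretic"`/`"nonparetic"`), `foot` (`"left"`/`"right"`),
#'   `start_index`, `end_index`, `start_time_s`, `end_time_s`,
#'   `stance_heel`, `valid`. Dropped candidates are available via
#'   [qc_report()].
#' @export
segment_steps <- function(trial, min_step_s = 0.2, max_step_s = 2.5, ...) {
  stopifnot(inherits(trial, "gait_trial"))
  side_of <- trial$meta$paretic_side %||% "left"
  tt <- trial$data$time
  onsets <- list(
    left  = detect_swing_onsets(marker_velocity(trial, "heel_left", "ap"),
                                trial$rate_hz, ...),
    right = detect_swing_onsets(marker_velocity(trial, "heel_right", "ap"),
                                trial$rate_hz, ...)
  )
  ev <- tibble(
    foot  = rep(c("left", "right"), lengths(onsets)),
    index = c(onsets$left, onsets$right)
  ) |>
    arrange(.data$index)
  if (nrow(ev) < 2L) abort("no steps detected: fewer than 2 swing onsets found.")

  qc <- list()
  rows <- vector("list", nrow(ev) - 1L)
  for (k in seq_len(nrow(ev) - 1L)) {
    this <- ev[k, ]
    nxt <- ev[k + 1L, ]
    if (nxt$foot == this$foot) {
      qc[[length(qc) + 1L]] <- list(
        time_s = tt[this$index], foot = this$foot,
        reason = "no intervening contralateral onset")
      next
    }
    dur <- tt[nxt$index] - tt[this$index]
    if (dur < min_step_s || dur > max_step_s) {
      qc[[length(qc) + 1L]] <- list(
        time_s = tt[this$index], foot = this$foot,
        reason = sprintf("duration %.3f s outside [%g, %g] s",
                         dur, min_step_s, max_step_s))
      next
    }
    rows[[k]] <- tibble(
      foot = this$foot,
      start_index = this$index, end_index = nxt$index,
      start_time_s = tt[this$index], end_time_s = tt[nxt$index],
      stance_heel = paste0("heel_", nxt$foot)
    )
  }
  steps <- list_rbind(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(steps) == 0L) abort("no steps detected: all candidates dropped.")
  steps <- steps |>
    mutate(
      step = dplyr::row_number(),
      side = ifelse(.data$foot == side_of, "paretic", "nonparetic"),
      valid = TRUE
    ) |>
    dplyr::relocate("step", "side")
  qc_tbl <- if (length(qc) > 0L) {
    list_rbind(lapply(qc, as_tibble))
  } else {
    tibble(time_s = double(), foot = character(), reason = character())
  }
  attr(steps, "qc") <- qc_tbl
  class(steps) <- c("step_table", class(steps))
  steps
}

#' QC report of dropped step candidates
#'
#' @param x A `step_table` from [segment_steps()].
#' @return Tibble with `time_s`, `foot`, `reason` for each dropped candidate.
#' @export
qc_report <- function(x) {
  attr(x, "qc") %||%
    tibble(time_s = double(), foot = character(), reason = character())
}

#' Count steps ending in a time window
#'
#' A step belongs to a window if its end time falls in the half-open
#' interval `[window[1], window[2])` — the step's width only exists at its
#' end, so the end time dates the step.
#'
#' @param steps A `step_table`.
#' @param window Numeric length-2 vector `c(start_s, end_s)`.
#' @return Integer count.
#' @export
steps_per_minute <- function(steps, window) {
  stopifnot(length(window) == 2L)
  sum(steps$end_time_s >= window[1L] & steps$end_time_s < window[2L])
}

# Minute index of each step (half-open minutes [60k, 60(k+1)), zero-based).
minute_of <- function(end_time_s) as.integer(floor(end_time_s / 60))
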