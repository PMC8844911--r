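# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

diff_series_for_test <- fpmod:::diff_series

# A default chronic-stroke-like 3-minute synthetic trial, rendered,
# filtered and analyzed with the marker pipeline.
synthetic_case <- function() {
  if (is.null(.fixtures$case)) {
    params <- gait_params(seed = 42)
    syn <- simulate_trial(params)
    filt <- lowpass_trial(syn$trial)
    metrics <- step_metrics(filt)
    .fixtures$case <- list(params = params, syn = syn, filt = filt,
                           metrics = metrics)
  }
  .fixtures$case
}

# Minimal trial with constant marker positions; enough frames for the
# filter/velocity machinery, at 120 Hz over `duration_s` seconds.
toy_trial <- function(duration_s = 2, rate_hz = 120,
                      sacrum_x = 0, heel_left_x = -0.1, heel_right_x = 0.1,
                      heel_left_y = 0, heel_right_y = 0,
                      paretic_side = "left", treadmill_speed_mps = 0.5) {
  n <- as.integer(duration_s * rate_hz) + 1L
  tt <- (seq_len(n) - 1L) / rate_hz
  rep_n <- function(v) if (length(v) == 1L) rep(v, n) else v
  gait_trial(
    tibble::tibble(
      time = tt,
      sacrum_x = rep_n(sacrum_x), sacrum_y = 0, sacrum_z = 1,
      heel_left_x = rep_n(heel_left_x), heel_left_y = rep_n(heel_left_y),
      heel_left_z = 0.05,
      heel_right_x = rep_n(heel_right_x), heel_right_y = rep_n(heel_right_y),
      heel_right_z = 0.05
    ),
    rate_hz = rate_hz,
    meta = list(paretic_side = paretic_side,
                treadmill_speed_mps = treadmill_speed_mps)
  )
}

# Hand-built step rows compatible with the spatial-metric functions.
toy_steps <- function(foot, start_time_s, end_time_s, rate_hz = 120,
                      paretic_side = "left") {
  other <- ifelse(foot == "left", "right", "left")
  tibble::tibble(
    step = seq_along(foot),
    side = ifelse(foot == paretic_side, "paretic", "nonparetic"),
    foot = foot,
    start_index = as.integer(round(start_time_s * rate_hz)) + 1L,
    end_index = as.integer(round(end_time_s * rate_hz)) + 1L,
    start_time_s = start_time_s,
    end_time_s = end_time_s,
    stance_heel = paste0("heel_", other),
    valid = TRUE
  )
}

# Mirror a trial in the mediolateral axis: negate every *_x channel and
# swap the left/right heel markers and the paretic side.
mirror_trial <- function(trial) {
  d <- trial$data
  for (cl in grep("_x$", names(d), value = TRUE)) d[[cl]] <- -d[[cl]]
  swap <- function(nm) {
    nm <- sub("heel_left", "HEEL_TMP", nm, fixed = TRUE)
    nm <- sub("heel_right", "heel_left", nm, fixed = TRUE)
    sub("HEEL_TMP", "heel_right", nm, fixed = TRUE)
  }
  names(d) <- swap(names(d))
  meta <- trial$meta
  meta$paretic_side <- ifelse(meta$paretic_side == "left", "right", "left")
  gait_trial(d, rate_hz = trial$rate_hz, meta = meta)
}
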