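test_that("swing onsets are posterior-to-anterior crossings", {
  # debounce window of 50 ms = 2 samples at 40 Hz
  expect_equal(detect_swing_onsets(c(-1, -1, 1, 1), 40), 3L)
  expect_equal(detect_swing_onsets(c(1, 1, 1, 1), 40), integer(0))
  expect_equal(detect_swing_onsets(c(-1, -1, -1), 40), integer(0))
})

test_that("debounce rejects blips and the refractory period merges chatter", {
  rate <- 120
  v <- rep(-0.5, rate)
  v[30] <- 0.1                     # single-sample blip: < 50 ms above zero
  expect_equal(detect_swing_onsets(v, rate), integer(0))

  v <- rep(-0.5, rate)
  v[30:50] <- 0.3                  # real crossing
  v[52:80] <- 0.3                  # re-crossing 22 samples later: inside refractory
  expect_equal(detect_swing_onsets(v, rate), 30L)

  v2 <- rep(-0.5, rate * 2)
  v2[30:50] <- 0.3
  v2[90:110] <- 0.3                # 60 samples (0.5 s) later: kept
  expect_equal(detect_swing_onsets(v2, rate), c(30L, 90L))
})

test_that("steps are segmented between ipsi- and contralateral onsets", {
  rate <- 120
  dur <- 3.4
  n <- as.integer(dur * rate) + 1L
  tt <- (seq_len(n) - 1L) / rate
  vel_profile <- function(on_times, swing = 0.4) {
    v <- rep(-0.1, n)
    for (t0 in on_times) v[tt >= t0 & tt < t0 + swing] <- 0.1
    cumsum(v) / rate
  }
  tr <- toy_trial(duration_s = dur)
  tr$data$heel_left_y <- vel_profile(c(1.0, 2.2))
  tr$data$heel_right_y <- vel_profile(1.6)

  steps <- segment_steps(tr)
  expect_equal(nrow(steps), 2L)
  expect_equal(steps$foot, c("left", "right"))
  expect_equal(steps$side, c("paretic", "nonparetic"))  # paretic side = left
  expect_equal(steps$start_time_s, c(1.0, 1.6), tolerance = 2 / rate)
  expect_equal(steps$end_time_s, c(1.6, 2.2), tolerance = 2 / rate)
  expect_equal(steps$stance_heel, c("heel_right", "heel_left"))
  # shared event: step 1 ends where step 2 starts
  expect_equal(steps$end_index[1], steps$start_index[2])
})

test_that("same-side consecutive onsets are dropped and QC-flagged", {
  rate <- 120
  dur <- 3.6
  n <- as.integer(dur * rate) + 1L
  tt <- (seq_len(n) - 1L) / rate
  vel_profile <- function(on_times) {
    v <- rep(-0.1, n)
    for (t0 in on_times) v[tt >= t0 & tt < t0 + 0.4] <- 0.1
    cumsum(v) / rate
  }
  tr <- toy_trial(duration_s = dur)
  tr$data$heel_left_y <- vel_profile(c(1.0, 2.2))   # two left onsets in a row
  tr$data$heel_right_y <- vel_profile(2.8)

  steps <- segment_steps(tr)
  expect_equal(nrow(steps), 1L)
  expect_equal(steps$foot, "left")
  qc <- qc_report(steps)
  expect_equal(nrow(qc), 1L)
  expect_match(qc$reason, "contralateral")
})

test_that("too few onsets is a fatal no-steps error", {
  tr <- toy_trial()
  tr$data$heel_left_y <- -0.1 * tr$data$time
  tr$data$heel_right_y <- -0.1 * tr$data$time
  expect_error(segment_steps(tr), "no steps detected")
})

test_that("steps_per_minute uses a half-open window on end times", {
  steps <- toy_steps(foot = c("left", "right", "left"),
                     start_time_s = c(58.0, 59.2, 59.6),
                     end_time_s = c(59.2, 59.6, 60.0))
  expect_equal(steps_per_minute(steps, c(0, 60)), 2L)
  expect_equal(steps_per_minute(steps, c(60, 120)), 1L)
})

test_that("the detector recovers programmed events on synthetic data", {
  case <- synthetic_case()
  steps <- segment_steps(case$filt)
  truth <- case$syn$truth
  expect_lte(abs(nrow(steps) - nrow(truth)), 1L)
  err_samples <- vapply(truth$start_time_s, function(t) {
    min(abs(steps$start_time_s - t)) * case$params$rate_hz
  }, numeric(1))
  expect_lte(max(err_samples), 1 + 1e-6)
  # side alternation holds for every retained consecutive pair
  expect_true(all(steps$foot[-1] != steps$foot[-nrow(steps)]))
  # programmed cadence 40/min: each full minute holds 39-41 steps
  counts <- vapply(0:2, function(k) {
    steps_per_minute(steps, c(60 * k, 60 * (k + 1)))
  }, integer(1))
  expect_true(all(counts[2] %in% 39:41))
})
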