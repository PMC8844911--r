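test_that("CSV round trip preserves the grid and positions", {
  params <- gait_params(duration_s = 30, seed = 1)
  syn <- simulate_trial(params)
  expect_equal(nrow(syn$trial$data), 30 * 120 + 1)

  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(syn$trial, path)
  back <- read_trial(path, "csv",
                     meta = list(paretic_side = "left",
                                 treadmill_speed_mps = 0.4))
  expect_equal(back$rate_hz, 120)
  expect_lt(max(abs(as.matrix(back$data) - as.matrix(syn$trial$data))), 1e-9)
})

test_that("TRC files are parsed with unit conversion to meters", {
  path <- withr::local_tempfile(fileext = ".trc")
  n <- 240
  tt <- (seq_len(n) - 1) / 120
  mk <- c("sacrum", "heel_left", "heel_right")
  hdr <- c(
    "PathFileType\t4\t(X/Y/Z)\ttoy.trc",
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    sprintf("120\t120\t%d\t3\tmm\t120\t1\t%d", n, n),
    paste(c("Frame#", "Time", as.vector(rbind(mk, "", ""))), collapse = "\t"),
    paste(c("", "", paste0(rep(c("X", "Y", "Z"), 3), rep(1:3, each = 3))),
          collapse = "\t")
  )
  pos_mm <- c(0, 10, 1000, -100, 5, 50, 100, 5, 50)  # constant per channel
  rows <- vapply(seq_len(n), function(i) {
    paste(c(i, sprintf("%.6f", tt[i]), sprintf("%.3f", pos_mm)), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)

  tr <- read_trial(path, "trc")
  expect_equal(tr$rate_hz, 120)
  expect_equal(tr$data$sacrum_z[1], 1.0)         # 1000 mm -> 1 m
  expect_equal(tr$data$heel_left_x[1], -0.1)     # -100 mm -> -0.1 m
})

test_that("a missing required marker is a fatal error naming it", {
  tr <- toy_trial()
  d <- tr$data[, !grepl("^heel_left", names(tr$data))]
  expect_error(gait_trial(d, 120), "heel_left")
})

test_that("non-uniform timestamps beyond tolerance are fatal", {
  tr <- toy_trial()
  d <- tr$data
  d$time[10] <- d$time[10] + 1e-6
  expect_error(gait_trial(d, 120), "Non-uniform")
})

test_that("short marker gaps are interpolated, long gaps are fatal", {
  tr <- toy_trial()
  d <- tr$data
  d$sacrum_x <- seq(0, 1, length.out = nrow(d))
  truth <- d$sacrum_x
  d$sacrum_x[50:55] <- NA  # 6 samples = 0.05 s
  repaired <- gait_trial(d, 120)
  expect_equal(repaired$data$sacrum_x, truth, tolerance = 1e-12)

  d$sacrum_x[50:70] <- NA  # 21 samples > 0.1 s
  expect_error(gait_trial(d, 120), "gap")
})

test_that("the zero-phase filter passes DC, keeps 1 Hz, kills 30 Hz", {
  rate <- 120
  tt <- (0:(rate * 10)) / rate
  interior <- seq(2 * rate, 8 * rate)

  expect_lt(max(abs(lowpass_series(rep(0.3, length(tt)), rate) - 0.3)), 1e-9)

  s1 <- sin(2 * pi * 1 * tt)
  f1 <- lowpass_series(s1, rate)
  amp1 <- max(abs(f1[interior]))
  expect_lt(abs(amp1 - 1), 0.01)

  s30 <- sin(2 * pi * 30 * tt)
  f30 <- lowpass_series(s30, rate)
  expect_lt(max(abs(f30[interior])), 0.05)

  expect_error(lowpass_series(s1, rate, cutoff_hz = 60), "Nyquist")
})

test_that("marker velocity matches analytic derivatives", {
  rate <- 120
  n <- 240
  tt <- (seq_len(n) - 1) / rate
  tr <- toy_trial()
  tr$data$sacrum_x <- 0.5 * tr$data$time
  expect_equal(marker_velocity(tr, "sacrum", "ml"),
               rep(0.5, nrow(tr$data)), tolerance = 1e-9)
  expect_equal(marker_velocity(tr, "heel_left", "ml"),
               rep(0, nrow(tr$data)), tolerance = 1e-12)

  tr$data$sacrum_y <- sin(2 * pi * 2 * tr$data$time)
  v <- marker_velocity(tr, "sacrum", "ap")
  v_true <- 2 * pi * 2 * cos(2 * pi * 2 * tr$data$time)
  inner <- 10:(nrow(tr$data) - 10)
  expect_lt(max(abs(v[inner] - v_true[inner])) / max(abs(v_true)), 0.02)

  expect_error(marker_velocity(tr, "knee", "ap"), "Unknown marker")
})

test_that("filtering and differentiation commute on interior samples", {
  rate <- 120
  set.seed(3)
  x <- cumsum(rnorm(rate * 5, sd = 0.001)) + sin(2 * pi * (1:(rate * 5)) / rate)
  a <- diff_series_for_test(lowpass_series(x, rate), rate)
  b <- lowpass_series(diff_series_for_test(x, rate), rate)
  inner <- (2 * rate):(3 * rate)
  expect_lt(max(abs(a[inner] - b[inner])), 1e-6)
})
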