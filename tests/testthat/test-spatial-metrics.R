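test_that("step width follows its definition and sign convention", {
  # right step: stance (left) heel at 0.00 at start, right heel at 0.15 at end
  tr <- toy_trial(heel_left_x = 0.00, heel_right_x = 0.15)
  st <- toy_steps("right", 0.5, 1.1)
  expect_equal(step_width(tr, st), 0.15)

  # both heels at the same mediolateral position
  tr0 <- toy_trial(heel_left_x = 0.05, heel_right_x = 0.05)
  expect_equal(step_width(tr0, st), 0)

  # crossover: right heel placed medial (left) of the stance heel
  tr_x <- toy_trial(heel_left_x = 0.00, heel_right_x = -0.04)
  expect_equal(step_width(tr_x, st), -0.04)

  # left-step mirror of the first case gives the same positive width
  tr_m <- toy_trial(heel_left_x = -0.15, heel_right_x = 0.00)
  st_l <- toy_steps("left", 0.5, 1.1)
  expect_equal(step_width(tr_m, st_l), 0.15)
})

test_that("step length accounts for belt travel", {
  # static heels, equal AP positions: belt term only
  tr <- toy_trial(treadmill_speed_mps = 0.5)
  st <- toy_steps(c("left", "right"), c(0.2, 1.0), c(1.0, 1.6))
  expect_equal(step_length(tr, st), c(NA, 0.5 * 0.6))

  # zero belt speed: pure marker AP difference
  tr2 <- toy_trial(heel_left_y = 0.10, heel_right_y = 0.45)
  expect_equal(step_length(tr2, st, treadmill_speed_mps = 0)[2], 0.35)
})

test_that("foot placement is signed side-symmetrically", {
  tr <- toy_trial(sacrum_x = 0, heel_right_x = 0.09)
  st_r <- toy_steps("right", 0.5, 1.1)
  expect_equal(foot_placement(tr, st_r), 0.09)

  tr_under <- toy_trial(sacrum_x = 0.02, heel_right_x = 0.02)
  expect_equal(foot_placement(tr_under, st_r), 0)

  tr_l <- toy_trial(sacrum_x = 0, heel_left_x = -0.09)
  st_l <- toy_steps("left", 0.5, 1.1)
  expect_equal(foot_placement(tr_l, st_l), 0.09)
})

test_that("pelvis curve is zero when the sacrum tracks the stance heel", {
  tr <- toy_trial(sacrum_x = 0.1, heel_right_x = 0.1)
  st <- toy_steps("left", 0.5, 1.1)   # stance heel = right
  cv <- pelvis_state_curve(tr, st)
  expect_length(cv$disp, 101)
  expect_equal(cv$disp, rep(0, 101))
  expect_equal(cv$vel, rep(0, 101))
})

test_that("rendered pelvis states are recovered at normalized time 0", {
  case <- synthetic_case()
  m <- case$metrics
  truth <- case$syn$truth
  expect_equal(nrow(m), nrow(truth))
  d0 <- vapply(m$pelvis_disp_m, `[`, numeric(1), 1L)
  v0 <- vapply(m$pelvis_vel_mps, `[`, numeric(1), 1L)
  expect_lt(max(abs(d0 - truth$d_m)), 0.003)
  expect_lt(max(abs(v0 - truth$v_mps)), 0.02)
})

test_that("the three mediolateral definitions are mutually consistent", {
  # signed width = foot placement + pelvis displacement at step end
  case <- synthetic_case()
  m <- case$metrics
  d_end <- vapply(m$pelvis_disp_m, `[`, numeric(1), 101L)
  gap <- m$step_width_m - (m$foot_placement_m + d_end)
  expect_lt(max(abs(gap)), 0.005)
})

test_that("mirroring the trial in ML leaves all metrics unchanged", {
  case <- synthetic_case()
  mirrored <- lowpass_trial(mirror_trial(case$syn$trial))
  m1 <- case$metrics
  m2 <- step_metrics(mirrored)
  expect_equal(nrow(m2), nrow(m1))
  expect_equal(m2$side, m1$side)   # sides follow the swapped paretic label
  expect_equal(m2$step_width_m, m1$step_width_m, tolerance = 1e-9)
  expect_equal(m2$foot_placement_m, m1$foot_placement_m, tolerance = 1e-9)
  expect_equal(m2$step_length_m, m1$step_length_m, tolerance = 1e-9)
  d1 <- vapply(m1$pelvis_disp_m, `[`, numeric(1), 51L)
  d2 <- vapply(m2$pelvis_disp_m, `[`, numeric(1), 51L)
  expect_equal(d2, d1, tolerance = 1e-9)
})

test_that("programmed spatial metrics are recovered from rendered markers", {
  case <- synthetic_case()
  m <- case$metrics
  truth <- case$syn$truth
  expect_lt(max(abs(m$step_width_m - truth$step_width_m)), 0.005)
  expect_lt(max(abs(m$step_length_m - truth$step_length_m), na.rm = TRUE), 0.005)
  n <- nrow(m)
  expect_lt(max(abs(m$foot_placement_m - truth$foot_placement_m)[-n]), 0.005)
})
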