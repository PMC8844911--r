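test_that("parameter validation enforces the model's domain", {
  expect_error(gait_params(cadence_spm = 20), "cadence")
  expect_error(gait_params(corr_dv = 1), "corr_dv")
  expect_error(gait_params(sigma_eps_m = 0), "positive")
  expect_error(gait_params(belt_speed_mps = 0), "belt_speed")
})

test_that("the analytic partial correlation obeys its limits", {
  p0 <- gait_params(beta_d = 0)
  expect_equal(true_partial_correlation(p0, "paretic"), 0)

  p_clean <- gait_params(sigma_eps_m = 1e-9)
  expect_gt(true_partial_correlation(p_clean, "paretic"), 0.999)

  # params_for_rho inverts the closed form
  for (rho in c(0, 0.3, 0.56, 0.8)) {
    pr <- params_for_rho(rho, gait_params())
    expect_equal(true_partial_correlation(pr, "paretic"), rho, tolerance = 1e-12)
  }
})

test_that("the closed form matches Monte-Carlo at large n", {
  p <- gait_params(seed = 11)
  st <- simulate_steps(p, 2e5)
  for (s in c("paretic", "nonparetic")) {
    sub <- st[st$side == s, ]
    mc <- partial_correlation(sub$step_width_m, sub$d_m, sub$v_mps)
    expect_equal(mc, true_partial_correlation(p, s), tolerance = 0.01)
  }
})

test_that("step draws are deterministic and statistically faithful", {
  p <- gait_params(seed = 123)
  a <- simulate_steps(p, 500)
  b <- simulate_steps(p, 500)
  expect_identical(a, b)

  # (d, v) covariance within 5% at n = 1e4
  p2 <- gait_params(seed = 77)
  st <- simulate_steps(p2, 1e4)
  expect_equal(sd(st$d_m), p2$sd_d_m, tolerance = 0.05)
  expect_equal(sd(st$v_mps), p2$sd_v_mps, tolerance = 0.05)
  expect_equal(cor(st$d_m, st$v_mps), p2$corr_dv, tolerance = 0.05)

  # null structure: no coupling -> no correlation
  p_null <- gait_params(beta_d = 0, beta_v = 0, seed = 5)
  st0 <- simulate_steps(p_null, 2e4)
  expect_lt(abs(cor(st0$step_width_m, st0$d_m)), 0.02)

  # sides alternate and honor the paretic label
  expect_true(all(st$foot[-1] != st$foot[-nrow(st)]))
  expect_equal(unique(st$side[st$foot == p2$paretic_side]), "paretic")
})

test_that("rendering is deterministic and kinematically feasible", {
  p <- gait_params(duration_s = 30, seed = 9)
  s1 <- simulate_trial(p)
  s2 <- simulate_trial(p)
  expect_identical(s1$trial$data, s2$trial$data)

  # infeasible swing (would be shorter than 2 samples)
  p_bad <- gait_params(duration_s = 30, rate_hz = 120)
  p_bad$swing_frac <- 0.01
  st <- simulate_steps(p_bad, 5)
  expect_error(render_trajectories(st, p_bad), "Infeasible")
})

test_that("heel AP velocity alternates posterior/anterior as designed", {
  case <- synthetic_case()
  v <- marker_velocity(case$filt, "heel_left", "ap")
  # long stance stretches at -belt speed, clear anterior excursions in swing
  expect_equal(stats::median(v[v < -0.1]), -case$params$belt_speed_mps,
               tolerance = 0.02)
  expect_gt(mean(v < -0.3), 0.5)   # most of the cycle is belt-driven stance
  expect_gt(max(v), case$params$belt_speed_mps)
})

test_that("the rho estimate rises over the step on rendered gait", {
  case <- synthetic_case()
  rc_p <- rho_curve(case$metrics, "paretic")
  rc_n <- rho_curve(case$metrics, "nonparetic")
  expect_gt(rc_p$rho[101], rc_p$rho[1])
  # paretic coupling is weaker by construction of the default preset
  expect_lt(rc_p$rho[1], rc_n$rho[1] + 0.05)

  # with an explicit within-step coupling ramp both sides rise
  p_ramp <- gait_params(coupling_ramp = 0.4, seed = 55)
  m_ramp <- step_metrics(lowpass_trial(simulate_trial(p_ramp)$trial))
  for (s in c("paretic", "nonparetic")) {
    rc <- rho_curve(m_ramp, s)
    expect_gt(rc$rho[101], rc$rho[1])
  }
})

test_that("the protocol has the published trial/period structure", {
  p <- gait_params(seed = 21)
  prot <- simulate_protocol(p, "perturbing", compliance_gain = 0.5)
  st <- prot$steps
  expect_equal(sort(unique(st$trial)), 1:3)
  # ~360 steps across three 3-minute trials at 40 steps/min
  expect_gt(nrow(st), 340)
  expect_lte(nrow(st), 366)
  expect_equal(unique(st$mode[st$trial == 1]), "normal")
  expect_equal(unique(st$mode[st$trial == 2]), "perturbing")
  expect_equal(unique(st$mode[st$trial == 3 & st$minute_in_trial < 2]),
               "perturbing")
  expect_equal(unique(st$mode[st$trial == 3 & st$minute_in_trial == 2]),
               "transparent")
  # global minutes 0..8, periods per the schedule
  expect_equal(sort(unique(st$global_minute)), 0:8)
  expect_equal(prot$minute_schedule$period,
               c(rep("Normal", 3), rep("Force", 5), "Transparent"))
  # transparent steps carry no force; forced steps do
  expect_true(all(st$force_n[st$mode %in% c("normal", "transparent")] == 0))
  expect_true(any(st$force_n[st$mode == "perturbing"] != 0))
})

test_that("zero compliance reproduces force-free walking exactly", {
  p <- gait_params(seed = 33)
  free <- simulate_protocol(p, "perturbing", compliance_gain = 0)
  half <- simulate_protocol(p, "perturbing", compliance_gain = 0.5)
  expect_equal(free$steps$step_width_m, free$steps$intended_width_m)
  # identical seeds give identical intended widths regardless of the field
  expect_equal(half$steps$intended_width_m, free$steps$intended_width_m)
  # and the transparent catch minute is untouched by the field
  tcatch <- half$steps$mode == "transparent"
  expect_equal(half$steps$step_width_m[tcatch],
               half$steps$intended_width_m[tcatch])
})

test_that("an after-effect shift alters coupling only in the catch minute", {
  p <- gait_params(seed = 14)
  prot <- simulate_protocol(p, "perturbing", compliance_gain = 0,
                            aftereffect_delta_beta_d = 0.5)
  base <- simulate_protocol(p, "perturbing", compliance_gain = 0)
  same <- prot$steps$mode != "transparent"
  expect_equal(prot$steps$step_width_m[same], base$steps$step_width_m[same])
  expect_false(isTRUE(all.equal(prot$steps$step_width_m[!same],
                                base$steps$step_width_m[!same])))
})
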