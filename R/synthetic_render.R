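#' Render step-level gait data into marker trajectories
#'
#' Produces continuous 120 Hz (by default) sacrum and heel trajectories
#' that realize a step-level table: each heel moves posteriorly with the
#' belt during stance and follows a raised-cosine anterior velocity pulse
#' during swing, constructed so the posterior-to-anterior zero crossing
#' falls exactly at the programmed step-start time; heel mediolateral
#' position transitions to each programmed placement during swing; the
#' sacrum mediolateral path is a cubic Hermite spline that passes through
#' every programmed step-start `(d, v)` state relative to the stance
#' heel. Ground-truth events and per-step metrics are returned alongside.
#'
#' @param step_table Output of [simulate_steps()] (column `step_width_m`
#'   may have been modified, e.g. by a force-field coupling).
#' @param params The `gait_params` used to generate the table.
#' @return A `synthetic_trial`: list with `trial` (a [gait_trial()]),
#'   `events` (tibble `foot`, `onset_time_s`) and `truth` (tibble of
#'   per-step ground-truth metrics: `step`, `side`, `foot`,
#'   `start_time_s`, `end_time_s`, `minute_index`, `d_m`, `v_mps`,
#'   `step_width_m`, `step_length_m`, `foot_placement_m`).
#' @export
render_trajectories <- function(step_table, params) {
  stopifnot(inherits(params, "gait_params"))
  n <- nrow(step_table)
  T_step <- 60 / params$cadence_spm
  s <- params$swing_frac * T_step
  v_belt <- params$belt_speed_mps
  rate <- params$rate_hz

  # pre-swing deceleration half-width: puts the velocity zero crossing of
  # the sin^2 pulse exactly at the nominal onset (net cycle displacement 0)
  arg <- v_belt * s / (2 * (2 * T_step * v_belt))
  w <- (s / pi) * asin(sqrt(arg))
  s_ml <- s - 2 * w                      # airborne window used for ML travel
  if (s_ml < 2 / rate) abort("Infeasible kinematics: swing shorter than 2 samples.")
  H <- 4 * T_step * v_belt / s           # pulse height

  t0 <- T_step
  onset_t <- t0 + (seq_len(n + 1L) - 1L) * T_step
  need <- onset_t[n + 1L] + s + 0.5
  duration <- max(params$duration_s, need)
  if (params$duration_s < need) {
    warn(sprintf("duration_s = %g s too short for %d steps; extended to %.1f s.",
                 params$duration_s, n, duration))
  }
  N <- as.integer(floor(duration * rate)) + 1L
  tt <- (seq_len(N) - 1L) / rate

  feet <- c(step_table$foot, setdiff(c("left", "right"), step_table$foot[n]))
  sgn <- ifelse(feet == "right", 1, -1)

  # ML placement bookkeeping -------------------------------------------------
  w_bar <- mean(step_table$step_width_m)
  ml_now <- c(left = -w_bar / 2, right = w_bar / 2)
  placed_ml <- numeric(n + 1L)           # landing ML of the swing foot of step k
  stance_ml <- numeric(n + 1L)           # stance-heel ML during step k
  widths <- c(step_table$step_width_m, w_bar)
  for (k in seq_len(n + 1L)) {
    fk <- feet[k]
    ck <- setdiff(c("left", "right"), fk)
    stance_ml[k] <- ml_now[[ck]]
    placed_ml[k] <- ml_now[[ck]] + sgn[k] * widths[k]
    ml_now[[fk]] <- placed_ml[k]
  }

  # heel trajectories --------------------------------------------------------
  home <- c(left = 0, right = params$ap_home_offset_m)
  pulse_int <- function(tau) tau / 2 - (s / (4 * pi)) * sin(2 * pi * tau / s)
  heel <- list()
  for (ft in c("left", "right")) {
    ks <- which(feet == ft)
    a <- onset_t[ks] - w                 # pulse start times
    y <- -v_belt * tt
    done <- findInterval(tt, a + s)      # completed pulses
    y <- y + H * (s / 2) * done
    for (j in seq_along(a)) {
      idx <- which(tt >= a[j] & tt < a[j] + s)
      y[idx] <- y[idx] + H * pulse_int(tt[idx] - a[j])
    }
    # anchor: position at end of first pulse equals the foot's AP home
    y <- y + home[[ft]] - (-v_belt * (a[1L] + s) + H * s / 2)

    x <- rep(if (ft == "left") -w_bar / 2 else w_bar / 2, N)
    z <- rep(0.05, N)
    prev_ml <- x[1L]
    for (j in seq_along(ks)) {
      k <- ks[j]
      idx_sw <- which(tt >= onset_t[k] & tt < onset_t[k] + s_ml)
      tau <- (tt[idx_sw] - onset_t[k]) / s_ml
      x[idx_sw] <- prev_ml + (placed_ml[k] - prev_ml) * (1 - cos(pi * tau)) / 2
      x[tt >= onset_t[k] + s_ml] <- placed_ml[k]
      idx_air <- which(tt >= onset_t[k] - w & tt < onset_t[k] - w + s)
      z[idx_air] <- 0.05 + 0.04 * sin(pi * (tt[idx_air] - onset_t[k] + w) / s)
      prev_ml <- placed_ml[k]
    }
    heel[[ft]] <- list(x = x, y = y, z = z)
  }

  # sacrum ML: Hermite spline through programmed step-start states -----------
  d_anchor <- c(step_table$d_m, params$mean_d_m)
  v_anchor <- c(step_table$v_mps, params$mean_v_mps)
  px <- stance_ml + sgn * d_anchor
  pv <- sgn * v_anchor
  sac_x <- numeric(N)
  before <- tt < onset_t[1L]
  sac_x[before] <- px[1L] - pv[1L] * (onset_t[1L] - tt[before])
  after <- tt >= onset_t[n + 1L]
  sac_x[after] <- px[n + 1L] + pv[n + 1L] * (tt[after] - onset_t[n + 1L])
  for (k in seq_len(n)) {
    idx <- which(tt >= onset_t[k] & tt < onset_t[k + 1L])
    u <- (tt[idx] - onset_t[k]) / T_step
    h00 <- 2 * u^3 - 3 * u^2 + 1
    h10 <- u^3 - 2 * u^2 + u
    h01 <- -2 * u^3 + 3 * u^2
    h11 <- u^3 - u^2
    sac_x[idx] <- h00 * px[k] + h10 * T_step * pv[k] +
      h01 * px[k + 1L] + h11 * T_step * pv[k + 1L]
  }

  data <- tibble(
    time = tt,
    sacrum_x = sac_x, sacrum_y = 0, sacrum_z = 1.0,
    heel_left_x = heel$left$x, heel_left_y = heel$left$y, heel_left_z = heel$left$z,
    heel_right_x = heel$right$x, heel_right_y = heel$right$y, heel_right_z = heel$right$z
  )
  trial <- gait_trial(data, rate_hz = rate,
                      meta = list(paretic_side = params$paretic_side,
                                  treadmill_speed_mps = v_belt))

  sl <- v_belt * T_step + home[feet[seq_len(n)]] -
    home[c(feet[2L], feet[seq_len(n - 1L)])]
  sl[1L] <- NA_real_
  truth <- tibble(
    step = step_table$step, side = step_table$side, foot = step_table$foot,
    start_time_s = onset_t[seq_len(n)], end_time_s = onset_t[2:(n + 1L)],
    minute_index = minute_of(onset_t[2:(n + 1L)]),
    d_m = step_table$d_m, v_mps = step_table$v_mps,
    step_width_m = step_table$step_width_m,
    step_length_m = unname(sl),
    foot_placement_m = d_anchor[2:(n + 1L)]
  )
  structure(
    list(trial = trial,
         events = tibble(foot = feet, onset_time_s = onset_t),
         truth = truth),
    class = "synthetic_trial"
  )
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("<synthetic_trial> %d programmed steps, %d rendered frames\n",
              nrow(x$truth), nrow(x$trial$data)))
  print(x$trial)
  invisible(x)
}

#' Number of steps that fit in a trial of given duration
#'
#' @param params A `gait_params`.
#' @return Integer step count such that the closing contralateral onset
#'   and swing still fit inside `duration_s`.
#' @export
n_steps_for_duration <- function(params) {
  T_step <- 60 / params$cadence_spm
  s <- params$swing_frac * T_step
  max(1L, as.integer(floor((params$duration_s - T_step - s - 0.5) / T_step)))
}

#' Simulate and render one complete trial
#'
#' Convenience wrapper: draws as many steps as fit in
#' `params$duration_s` with [simulate_steps()] and renders them with
#' [render_trajectories()].
#'
#' @param params A `gait_params`.
#' @return A `synthetic_trial`.
#' @export
simulate_trial <- function(params) {
  steps <- simulate_steps(params, n_steps_for_duration(params))
  render_trajectories(steps, params)
}
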