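#' Simulate the full force-field exposure protocol
#'
#' Emulates the three-trial session: a 3-minute Normal trial, a 3-minute
#' trial with the force-field in assistive or perturbing mode, and a
#' third trial with 2 minutes of forces followed by a 1-minute
#' transparent catch period. The controller's baseline step width
#' `SW_mean` is the mean of the last 50 Normal steps. Force action on the
#' swing leg is abstracted into a single compliance gain `g`: the
#' realized step width is `intended + g * (target - intended)`, the
#' controller target coming from the control equation with the mode's
#' speed-interpolated coefficients.
#'
#' @param params A `gait_params` (its `duration_s` is the per-trial
#'   duration; `seed` seeds the whole protocol).
#' @param mode `"assistive"` or `"perturbing"` group assignment.
#' @param schedule A `coefficient_schedule` (default [default_schedule()]).
#' @param compliance_gain Fraction of the controller's pull realized in
#'   the step width, in `[0, 1]`.
#' @param render If `TRUE`, marker trajectories are rendered for each
#'   trial (slower); otherwise the protocol stays at step level.
#' @param aftereffect_delta_beta_d Shift added to both sides' `beta_d`
#'   for steps in the transparent catch minute, to emulate an
#'   after-effect in the pelvis-to-step-width coupling.
#' @return An `fpm_protocol`: list with `steps` (combined step-level
#'   tibble with intended and realized widths, controller target/force,
#'   mode, times and global minute), `trials` (list of `synthetic_trial`
#'   when rendered, else `NULL`), `minute_schedule` (global minute to
#'   period map), `sw_mean`, `mode`, `compliance_gain`, `params`.
#' @export
simulate_protocol <- function(params, mode = c("perturbing", "assistive"),
                              schedule = default_schedule(),
                              compliance_gain = 0.5, render = FALSE,
                              aftereffect_delta_beta_d = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "gait_params"))
  if (compliance_gain < 0 || compliance_gain > 1) {
    abort("compliance_gain must be in [0, 1].")
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  T_step <- 60 / params$cadence_spm
  n_tr <- n_steps_for_duration(params)
  end_times <- (seq_len(n_tr) + 1L) * T_step
  minute_in_trial <- minute_of(end_times)
  ctrl_ab <- interpolate_coefficients(schedule, mode, params$belt_speed_mps)

  other_foot <- function(f) setdiff(c("left", "right"), f)

  # trial 1: Normal ----------------------------------------------------------
  s1 <- simulate_steps(params, n_tr, .set_seed = FALSE) |>
    mutate(intended_width_m = .data$step_width_m,
           mode = "normal", target_m = NA_real_, force_n = 0)
  sw_mean <- mean(utils::tail(s1$step_width_m, 50))

  apply_field <- function(steps, step_mode) {
    target <- target_step_width(ctrl_ab[["A"]], ctrl_ab[["B"]],
                                steps$d_m, sw_mean)
    realized <- steps$step_width_m +
      compliance_gain * (target - steps$step_width_m)
    on <- step_mode != "transparent"
    steps |>
      mutate(
        intended_width_m = .data$step_width_m,
        mode = step_mode,
        target_m = ifelse(on, target, .data$step_width_m),
        step_width_m = ifelse(on, realized, .data$step_width_m),
        force_n = ifelse(on, spring_force(target, .data$step_width_m), 0)
      )
  }

  # trial 2: forces throughout -----------------------------------------------
  s2 <- simulate_steps(params, n_tr, .set_seed = FALSE) |>
    apply_field(rep(mode, n_tr))

  # trial 3: 2 minutes of forces, then the transparent catch minute ----------
  in_catch <- minute_in_trial >= 2L
  n_force <- sum(!in_catch)
  p_force <- params
  p_force$start_foot <- params$start_foot
  s3a <- simulate_steps(p_force, n_force, .set_seed = FALSE)
  p_catch <- params
  p_catch$beta_d <- params$beta_d + aftereffect_delta_beta_d
  p_catch$start_foot <- other_foot(s3a$foot[n_force])
  s3b <- simulate_steps(p_catch, n_tr - n_force, .set_seed = FALSE) |>
    mutate(step = .data$step + n_force)
  s3 <- bind_rows(s3a, s3b) |>
    apply_field(ifelse(in_catch, "transparent", mode))

  trials_steps <- list(s1, s2, s3)
  combined <- purrr::imap(trials_steps, function(st, j) {
    st |>
      mutate(trial = j,
             start_time_s = .data$step * T_step,
             end_time_s = (.data$step + 1L) * T_step,
             minute_in_trial = minute_of(.data$end_time_s),
             global_minute = 3L * (j - 1L) + .data$minute_in_trial)
  }) |>
    list_rbind()

  rendered <- NULL
  if (render) {
    rendered <- lapply(trials_steps, function(st) {
      render_trajectories(st, params)
    })
  }

  minute_schedule <- protocol_schedule()
  structure(
    list(steps = combined, trials = rendered,
         minute_schedule = minute_schedule,
         sw_mean = sw_mean, mode = mode,
         compliance_gain = compliance_gain, params = params),
    class = "fpm_protocol"
  )
}

#' Global minute-to-period map of the three-trial protocol
#'
#' Minutes 0-2 are the Normal baseline, minutes 3-7 the five minutes with
#' assistance or perturbations applied (all of trial 2 plus the first two
#' minutes of trial 3), and minute 8 the transparent catch minute closing
#' trial 3.
#'
#' @return Tibble with `trial`, `minute_in_trial`, `minute_index`
#'   (global), `period`.
#' @export
protocol_schedule <- function() {
  tibble(
    trial = rep(1:3, each = 3L),
    minute_in_trial = rep(0:2, 3L),
    minute_index = 0:8,
    period = c(rep("Normal", 3L), rep("Force", 5L), "Transparent")
  )
}

#' Per-minute step-start rho_disp from a step-level table
#'
#' Measures, for each global minute and side, the partial correlation of
#' realized step width with pelvis displacement controlling for velocity
#' over the steps of that minute — the step-level counterpart of the
#' marker pipeline's per-minute step-start rho_disp.
#'
#' @param steps Step-level tibble with `global_minute`, `side`, `d_m`,
#'   `v_mps`, `step_width_m` (e.g. `protocol$steps`).
#' @param min_steps Minimum steps per side per minute (default 10).
#' @return Tibble with `side`, `minute_index`, `n_steps`, `rho_start`.
#' @export
minute_rho_steps <- function(steps, min_steps = 10L) {
  steps |>
    dplyr::group_by(side = .data$side, minute_index = .data$global_minute) |>
    dplyr::summarise(
      n_steps = dplyr::n(),
      rho_start = if (dplyr::n() >= min_steps) {
        partial_correlation(.data$step_width_m, .data$d_m, .data$v_mps)
      } else NA_real_,
      .groups = "drop"
    )
}

#' Period means of step-level measured rho_disp for a protocol
#'
#' Averages [minute_rho_steps()] over the protocol's period schedule,
#' per side.
#'
#' @param protocol An `fpm_protocol`.
#' @param min_steps Minimum steps per side per minute.
#' @return Tibble with `period`, `side`, `n_minutes`, `rho_start`,
#'   `mean_step_width_m`.
#' @export
protocol_period_means <- function(protocol, min_steps = 10L) {
  pm <- minute_rho_steps(protocol$steps, min_steps)
  widths <- protocol$steps |>
    dplyr::group_by(side = .data$side, minute_index = .data$global_minute) |>
    dplyr::summarise(mean_step_width_m = mean(.data$step_width_m),
                     .groups = "drop")
  pm |>
    dplyr::inner_join(widths, by = c("side", "minute_index")) |>
    dplyr::inner_join(protocol$minute_schedule[, c("minute_index", "period")],
                      by = "minute_index") |>
    dplyr::group_by(.data$period, .data$side) |>
    dplyr::summarise(
      n_minutes = dplyr::n(),
      rho_start = mean(.data$rho_start, na.rm = TRUE),
      mean_step_width_m = mean(.data$mean_step_width_m),
      .groups = "drop"
    )
}
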