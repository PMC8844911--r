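#' Parameters of the synthetic step-level gait model
#'
#' The generator draws, for every step, a pelvis state at step start —
#' displacement `d` (m) and velocity `v` (m/s) away from the stance foot,
#' jointly Gaussian — and a signed step width from the linear model
#' `SW = beta0 + beta_d * d + beta_v * v + eps`, with side-specific
#' coupling coefficients (a weakened paretic `beta_d` is the
#' chronic-stroke-like default). `coupling_ramp` adds an extra dependence
#' of the width on the upcoming pelvis end-state, strengthening the
#' width-to-pelvis link toward the end of the step in rendered data.
#'
#' @param beta0_m Baseline step width (m).
#' @param beta_d Coupling of width to pelvis displacement (per m); named
#'   vector `c(paretic = , nonparetic = )` or scalar for both sides.
#' @param beta_v Coupling of width to pelvis velocity (per m/s); same shape.
#' @param sigma_eps_m SD of foot-placement noise (m).
#' @param sd_d_m,sd_v_mps,corr_dv Pelvis state covariance at step start.
#' @param mean_d_m,mean_v_mps Pelvis state means at step start.
#' @param cadence_spm Total steps per minute, in the 25-52 range typical
#'   of slow treadmill walking post-stroke.
#' @param belt_speed_mps Treadmill belt speed (> 0).
#' @param rate_hz Marker sampling rate (default 120).
#' @param duration_s Trial duration (default 180, a 3-minute trial).
#' @param paretic_side `"left"` or `"right"`.
#' @param start_foot Foot taking the first step.
#' @param swing_frac Swing time as a fraction of step duration.
#' @param ap_home_offset_m Anterior offset of the right heel's landing
#'   anchor relative to the left's; shifts per-side step lengths.
#' @param coupling_ramp Weight (per m) of the upcoming pelvis end-state in
#'   the width model (0 disables it).
#' @param seed Optional RNG seed used by the simulation functions.
#' @return A validated `gait_params` list.
#' @export
gait_params <- function(beta0_m = 0.12,
                        beta_d = c(paretic = 0.45, nonparetic = 0.75),
                        beta_v = c(paretic = 0.10, nonparetic = 0.10),
                        sigma_eps_m = 0.015,
                        sd_d_m = 0.02, sd_v_mps = 0.05, corr_dv = 0.4,
                        mean_d_m = 0.06, mean_v_mps = 0.02,
                        cadence_spm = 40, belt_speed_mps = 0.4,
                        rate_hz = 120, duration_s = 180,
                        paretic_side = "left", start_foot = "left",
                        swing_frac = 0.4, ap_home_offset_m = 0,
                        coupling_ramp = 0, seed = NULL) {
  both_sides <- function(v, nm) {
    if (length(v) == 1L && is.null(names(v))) {
      v <- c(paretic = unname(v), nonparetic = unname(v))
    }
    if (!all(c("paretic", "nonparetic") %in% names(v))) {
      abort(paste0("`", nm, "` must be a scalar or named c(paretic=, nonparetic=)."))
    }
    v[c("paretic", "nonparetic")]
  }
  p <- list(
    beta0_m = beta0_m,
    beta_d = both_sides(beta_d, "beta_d"),
    beta_v = both_sides(beta_v, "beta_v"),
    sigma_eps_m = sigma_eps_m,
    sd_d_m = sd_d_m, sd_v_mps = sd_v_mps, corr_dv = corr_dv,
    mean_d_m = mean_d_m, mean_v_mps = mean_v_mps,
    cadence_spm = cadence_spm, belt_speed_mps = belt_speed_mps,
    rate_hz = rate_hz, duration_s = duration_s,
    paretic_side = paretic_side, start_foot = start_foot,
    swing_frac = swing_frac, ap_home_offset_m = ap_home_offset_m,
    coupling_ramp = coupling_ramp, seed = seed
  )
  if (p$sd_d_m <= 0 || p$sd_v_mps <= 0 || p$sigma_eps_m <= 0) {
    abort("sd_d_m, sd_v_mps and sigma_eps_m must be positive.")
  }
  if (abs(p$corr_dv) >= 1) abort("|corr_dv| must be below 1.")
  if (p$cadence_spm < 25 || p$cadence_spm > 52) {
    abort("cadence_spm must lie in [25, 52] steps/min.")
  }
  if (p$belt_speed_mps <= 0) abort("belt_speed_mps must be positive.")
  if (!p$paretic_side %in% c("left", "right")) abort("paretic_side must be left/right.")
  if (!p$start_foot %in% c("left", "right")) abort("start_foot must be left/right.")
  if (p$swing_frac <= 0 || p$swing_frac >= 1) abort("swing_frac must be in (0, 1).")
  if (p$coupling_ramp < 0) abort("coupling_ramp must be >= 0.")
  structure(p, class = "gait_params")
}

#' Analytic step-start partial correlation of the generator
#'
#' Closed form for the step-level model `SW = beta0 + beta_d d + beta_v v
#' + gamma u + eps` with `(d, v)` jointly Gaussian and `u` (the pelvis
#' end-state term, weight `gamma = coupling_ramp`) independent of `(d, v)`
#' with SD `sd_d_m`:
#' `rho* = beta_d s / sqrt(beta_d^2 s^2 + gamma^2 sd_d^2 + sigma_eps^2)`
#' where `s^2 = sd_d^2 (1 - corr_dv^2)` is the conditional variance of
#' displacement given velocity.
#'
#' @param params A `gait_params`.
#' @param side `"paretic"` or `"nonparetic"`.
#' @return The true partial correlation, a dimensionless value in `[-1, 1]`.
#' @export
true_partial_correlation <- function(params, side = c("paretic", "nonparetic")) {
  side <- match.arg(side)
  bd <- params$beta_d[[side]]
  s2 <- params$sd_d_m^2 * (1 - params$corr_dv^2)
  noise2 <- params$coupling_ramp^2 * params$sd_d_m^2 + params$sigma_eps_m^2
  bd * sqrt(s2) / sqrt(bd^2 * s2 + noise2)
}

#' Choose displacement couplings for a target partial correlation
#'
#' Inverts [true_partial_correlation()] for `beta_d`, holding the noise
#' and pelvis-state parameters fixed, and sets both sides to the value
#' that yields the requested step-start partial correlation.
#'
#' @param rho Target partial correlation in `[0, 1)`.
#' @param params A `gait_params` to modify.
#' @return The modified `gait_params`.
#' @export
params_for_rho <- function(rho, params = gait_params()) {
  if (rho < 0 || rho >= 1) abort("`rho` must be in [0, 1).")
  s <- params$sd_d_m * sqrt(1 - params$corr_dv^2)
  noise <- sqrt(params$coupling_ramp^2 * params$sd_d_m^2 + params$sigma_eps_m^2)
  bd <- rho / sqrt(1 - rho^2) * noise / s
  params$beta_d <- c(paretic = bd, nonparetic = bd)
  params
}

#' Draw step-level gait data from the generator model
#'
#' Sides alternate starting from `params$start_foot`; each step's pelvis
#' start state and signed width are drawn from the side-specific linear
#' model. Setting `params$seed` makes the draw reproducible.
#'
#' @param params A `gait_params`.
#' @param n_steps Number of steps (>= 1).
#' @param .set_seed Whether to seed the RNG from `params$seed` (default);
#'   internal callers that manage the RNG stream pass `FALSE`.
#' @return Tibble with columns `step`, `foot`, `side`, `d_m`, `v_mps`,
#'   `step_width_m`.
#' @export
simulate_steps <- function(params, n_steps, .set_seed = TRUE) {
  stopifnot(inherits(params, "gait_params"), n_steps >= 1L)
  if (.set_seed && !is.null(params$seed)) set.seed(params$seed)
  n <- as.integer(n_steps)
  feet <- rep_len(if (params$start_foot == "left") c("left", "right")
                  else c("right", "left"), n)
  side <- ifelse(feet == params$paretic_side, "paretic", "nonparetic")
  z1 <- rnorm(n + 1L)
  z2 <- rnorm(n + 1L)
  d_all <- params$mean_d_m + params$sd_d_m * z1
  v_all <- params$mean_v_mps +
    params$sd_v_mps * (params$corr_dv * z1 + sqrt(1 - params$corr_dv^2) * z2)
  d <- d_all[seq_len(n)]
  v <- v_all[seq_len(n)]
  eps <- rnorm(n, 0, params$sigma_eps_m)
  u <- -(d_all[2:(n + 1L)] - params$mean_d_m)  # upcoming end-state term
  sw <- params$beta0_m +
    params$beta_d[side] * d + params$beta_v[side] * v +
    params$coupling_ramp * u + eps
  tibble(step = seq_len(n), foot = feet, side = side,
         d_m = d, v_mps = v, step_width_m = unname(sw))
}
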