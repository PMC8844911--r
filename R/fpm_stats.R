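#' Pearson partial correlation
#'
#' Partial correlation of `y` and `x` controlling for a single covariate
#' `z`: `(r_yx - r_yz * r_xz) / sqrt((1 - r_yz^2) * (1 - r_xz^2))`. This
#' is the statistic behind rho_disp, with `y` the step widths, `x` the
#' pelvis displacements and `z` the pelvis velocities at one normalized
#' time point.
#'
#' @param y,x,z Equal-length numeric vectors.
#' @return A single correlation in `[-1, 1]`, or `NA` when any input has
#'   (near) zero variance or a control correlation is degenerate
#'   (`|r| >= 1`) — never a silently propagated NaN.
#' @export
partial_correlation <- function(y, x, z) {
  n <- length(y)
  if (length(x) != n || length(z) != n) abort("y, x, z must have equal length.")
  if (n < 3L) return(NA_real_)
  if (anyNA(y) || anyNA(x) || anyNA(z)) return(NA_real_)
  if (sd(y) == 0 || sd(x) == 0 || sd(z) == 0) return(NA_real_)
  r_yx <- cor(y, x)
  r_yz <- cor(y, z)
  r_xz <- cor(x, z)
  den2 <- (1 - r_yz^2) * (1 - r_xz^2)
  if (!is.finite(den2) || den2 <= 0) return(NA_real_)
  out <- (r_yx - r_yz * r_xz) / sqrt(den2)
  # guard rounding just past +/-1
  max(-1, min(1, out))
}

#' rho_disp across normalized step time
#'
#' For one side and one analysis window, computes at every normalized time
#' point `k = 0..100` the partial correlation between step width and
#' pelvis displacement at `k`, controlling for pelvis velocity at `k`.
#' `rho[0]` is the step-start rho_disp (the primary outcome scale);
#' `rho[100]` is the step-end value.
#'
#' @param metrics A `step_metrics` table.
#' @param side `"paretic"` or `"nonparetic"`.
#' @param window Optional `c(start_s, end_s)`; steps are kept when their
#'   end time falls in the half-open window.
#' @param min_steps Minimum number of steps for a defined correlation;
#'   fewer yields an all-`NA` curve flagged undefined.
#' @return Tibble (class `rho_curve`) with columns `pct` (0..100) and
#'   `rho`, and attributes `side`, `window`, `n_steps`.
#' @export
rho_curve <- function(metrics, side = c("paretic", "nonparetic"),
                      window = NULL, min_steps = 10L) {
  side <- match.arg(side)
  sel <- metrics$side == side
  if (!is.null(window)) {
    sel <- sel & metrics$end_time_s >= window[1L] & metrics$end_time_s < window[2L]
  }
  sub <- metrics[sel, ]
  n <- nrow(sub)
  n_pts <- if (n > 0L) length(sub$pelvis_disp_m[[1L]]) else 101L
  rho <- rep(NA_real_, n_pts)
  if (n >= min_steps) {
    disp <- do.call(rbind, sub$pelvis_disp_m)
    vel <- do.call(rbind, sub$pelvis_vel_mps)
    w <- sub$step_width_m
    rho <- vapply(seq_len(n_pts), function(k) {
      partial_correlation(w, disp[, k], vel[, k])
    }, numeric(1))
  }
  out <- tibble(pct = seq(0L, length.out = n_pts,
                          by = as.integer(100 / (n_pts - 1L))), rho = rho)
  attr(out, "side") <- side
  attr(out, "window") <- window
  attr(out, "n_steps") <- n
  class(out) <- c("rho_curve", class(out))
  out
}

#' Per-minute gait metrics
#'
#' Computes, for each side and each half-open minute of the trial, the
#' step-start and step-end rho_disp and the mean signed step width, step
#' length, and foot placement. Minutes with fewer than `min_steps` steps
#' of a side get `NA` correlations for that side.
#'
#' @param metrics A `step_metrics` table.
#' @param min_steps Minimum steps per side per minute for a defined
#'   correlation (default 10).
#' @return Tibble with columns `side`, `minute_index`, `n_steps`,
#'   `rho_start`, `rho_end`, `mean_step_width_m`, `mean_step_length_m`,
#'   `mean_foot_placement_m`.
#' @export
per_minute_metrics <- function(metrics, min_steps = 10L) {
  metrics |>
    as_tibble() |>
    dplyr::group_by(.data$side, .data$minute_index) |>
    dplyr::group_modify(function(g, key) {
      n <- nrow(g)
      rho0 <- rho_last <- NA_real_
      if (n >= min_steps) {
        disp <- do.call(rbind, g$pelvis_disp_m)
        vel <- do.call(rbind, g$pelvis_vel_mps)
        k_last <- ncol(disp)
        rho0 <- partial_correlation(g$step_width_m, disp[, 1L], vel[, 1L])
        rho_last <- partial_correlation(g$step_width_m, disp[, k_last], vel[, k_last])
      }
      tibble(
        n_steps = n,
        rho_start = rho0,
        rho_end = rho_last,
        mean_step_width_m = mean(g$step_width_m),
        mean_step_length_m = mean(g$step_length_m, na.rm = TRUE),
        mean_foot_placement_m = mean(g$foot_placement_m)
      )
    }) |>
    dplyr::ungroup()
}

#' Aggregate per-minute metrics into protocol periods
#'
#' Averages each per-minute metric over the minutes belonging to each
#' protocol period (e.g. the three Normal minutes, the five minutes with
#' forces applied, and the single transparent catch minute). Minutes with
#' an undefined correlation are excluded from that correlation's mean.
#'
#' @param per_minute Output of [per_minute_metrics()].
#' @param schedule Data frame mapping `minute_index` to `period` labels;
#'   every scheduled minute must be present in `per_minute`.
#' @return Tibble (class `period_summary`) with one row per period and
#'   side, carrying the period means of every metric and the minute count.
#' @export
period_summary <- function(per_minute, schedule) {
  schedule <- as_tibble(schedule)
  if (!all(c("minute_index", "period") %in% names(schedule))) {
    abort("`schedule` needs columns `minute_index` and `period`.")
  }
  missing_min <- setdiff(schedule$minute_index, per_minute$minute_index)
  if (length(missing_min) > 0L) {
    abort(paste0("Scheduled minute(s) absent from per-minute metrics: ",
                 paste(sort(missing_min), collapse = ", ")))
  }
  out <- per_minute |>
    dplyr::inner_join(schedule, by = "minute_index") |>
    dplyr::group_by(.data$period, .data$side) |>
    dplyr::summarise(
      n_minutes = dplyr::n(),
      rho_start = mean(.data$rho_start, na.rm = TRUE),
      rho_end = mean(.data$rho_end, na.rm = TRUE),
      mean_step_width_m = mean(.data$mean_step_width_m),
      mean_step_length_m = mean(.data$mean_step_length_m, na.rm = TRUE),
      mean_foot_placement_m = mean(.data$mean_foot_placement_m),
      .groups = "drop"
    ) |>
    mutate(dplyr::across(dplyr::where(is.numeric), ~ replace(.x, is.nan(.x), NA_real_)))
  class(out) <- c("period_summary", class(out))
  out
}

#' Eligibility screen on step-start paretic rho_disp
#'
#' Participants qualify for force-field training when their baseline
#' step-start paretic rho_disp during normal walking falls strictly below
#' 0.56 — the lower bound of the 95% confidence interval for this metric
#' in neurologically-intact adults at preferred speed — indicating a
#' weakened pelvis-to-step-width link.
#'
#' @param step_start_paretic_rho Baseline rho value (scalar).
#' @param threshold Screening threshold (default 0.56).
#' @return One-row tibble with `eligible`, `rho`, `threshold`, `reason`.
#' @export
inclusion_screen <- function(step_start_paretic_rho, threshold = 0.56) {
  rho <- step_start_paretic_rho
  if (length(rho) != 1L) abort("Provide a single rho value.")
  if (!is.finite(rho)) {
    return(tibble(eligible = FALSE, rho = NA_real_, threshold = threshold,
                  reason = "rho undefined"))
  }
  tibble(
    eligible = rho < threshold,
    rho = rho,
    threshold = threshold,
    reason = ifelse(rho < threshold, "below threshold",
                    "at or above threshold (strict inequality required)")
  )
}
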