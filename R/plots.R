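#' Plot a rho_disp curve over normalized step time
#'
#' @param object A `rho_curve` from [rho_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rho_curve <- function(object, ...) {
  lab <- sprintf("%s side, n = %d steps",
                 attr(object, "side"), attr(object, "n_steps"))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pct, y = .data$rho)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = "Normalized step time (%)",
                  y = expression(rho["disp"]),
                  title = "Step width vs pelvis displacement (partial correlation)",
                  subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Plot period means of a metric by side
#'
#' @param object A `period_summary` from [period_summary()].
#' @param metric Column to display (default `"rho_start"`).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.period_summary <- function(object, metric = "rho_start", ...) {
  df <- as_tibble(object) |>
    mutate(period = factor(.data$period,
                           levels = c("Normal", "Force", "Transparent")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period, y = .data[[metric]],
                                   group = .data$side, colour = .data$side)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = metric, colour = "side") +
    ggplot2::theme_minimal()
}

#' Plot marker mediolateral trajectories of a trial segment
#'
#' Quick visual QC of a trial: heel and sacrum ML positions against time.
#'
#' @param trial A `gait_trial`.
#' @param from_s,to_s Time window to display (default first 10 s).
#' @return A ggplot.
#' @export
plot_trial_ml <- function(trial, from_s = 0, to_s = 10) {
  stopifnot(inherits(trial, "gait_trial"))
  df <- trial$data |>
    dplyr::filter(.data$time >= from_s, .data$time <= to_s) |>
    select("time", dplyr::ends_with("_x")) |>
    pivot_longer(-"time", names_to = "marker", values_to = "ml_m") |>
    mutate(marker = sub("_x$", "", .data$marker))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$ml_m,
                                   colour = .data$marker)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Mediolateral position (m)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
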