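#' Analyze a participant's session
#'
#' Runs the full marker pipeline over a session of 3-minute trials:
#' low-pass filtering, gait event detection, per-step spatial metrics and
#' pelvis state curves, per-minute metrics, and period aggregation over
#' the protocol schedule. Optionally writes the per-minute table, the
#' period summary, the per-period rho_disp curves and a QC report to an
#' output directory as CSV/JSON.
#'
#' @param trials A list of `gait_trial` objects (one per 3-minute trial,
#'   in protocol order), or a `synthetic_trial`/`fpm_protocol` with
#'   rendered trials.
#' @param schedule Protocol schedule as from [protocol_schedule()]
#'   (columns `trial`, `minute_in_trial`, `minute_index`, `period`).
#' @param cutoff_hz Low-pass filter cutoff (default 10 Hz).
#' @param min_steps Minimum steps per side per minute for a defined
#'   correlation (default 10).
#' @param out_dir Optional output directory; created if needed.
#' @return List (class `fpm_analysis`) with `per_minute`, `summary` (a
#'   [period_summary()]), `rho_curves` (per period, side and normalized
#'   time point, averaged over the period's minutes), `inclusion` (the
#'   baseline screen on Normal step-start paretic rho_disp), and `qc`.
#' @export
run_analyze <- function(trials, schedule = protocol_schedule(),
                        cutoff_hz = 10, min_steps = 10L, out_dir = NULL) {
  if (inherits(trials, "fpm_protocol")) {
    if (is.null(trials$trials)) {
      abort("This protocol was simulated without rendering; rerun simulate_protocol(render = TRUE).")
    }
    trials <- lapply(trials$trials, function(x) x$trial)
  }
  if (inherits(trials, "synthetic_trial")) trials <- list(trials$trial)
  if (inherits(trials, "gait_trial")) trials <- list(trials)
  schedule <- as_tibble(schedule)

  per_trial <- purrr::imap(trials, function(tr, j) {
    filt <- lowpass_trial(tr, cutoff_hz = cutoff_hz)
    m <- step_metrics(filt)
    list(metrics = m |> mutate(trial = j), qc = qc_report(m) |> mutate(trial = j))
  })
  metrics <- purrr::map(per_trial, "metrics") |> list_rbind()
  qc <- purrr::map(per_trial, "qc") |> list_rbind()

  per_minute <- metrics |>
    dplyr::group_by(.data$trial) |>
    dplyr::group_modify(function(g, key) {
      class(g) <- c("step_metrics", class(g))
      per_minute_metrics(g, min_steps = min_steps) |>
        dplyr::rename(minute_in_trial = "minute_index")
    }) |>
    dplyr::ungroup() |>
    dplyr::inner_join(schedule, by = c("trial", "minute_in_trial"))

  summary <- period_summary(
    per_minute |> select(-"minute_in_trial", -"trial", -"period"),
    schedule[, c("minute_index", "period")]
  )

  curves <- metrics |>
    select(-"minute_index") |>
    mutate(minute_in_trial = minute_of(.data$end_time_s)) |>
    dplyr::inner_join(schedule, by = c("trial", "minute_in_trial")) |>
    dplyr::group_by(.data$period, .data$side, .data$minute_index) |>
    dplyr::group_modify(function(g, key) {
      g$side <- key$side
      class(g) <- c("step_metrics", class(g))
      rc <- rho_curve(g, side = key$side, min_steps = min_steps)
      tibble(pct = rc$pct, rho = rc$rho, n_steps = attr(rc, "n_steps"))
    }) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$period, .data$side, .data$pct) |>
    dplyr::summarise(rho = mean(.data$rho, na.rm = TRUE),
                     n_minutes = dplyr::n(), .groups = "drop") |>
    mutate(rho = replace(.data$rho, is.nan(.data$rho), NA_real_))

  normal_rho <- summary$rho_start[summary$period == "Normal" &
                                    summary$side == "paretic"]
  inclusion <- inclusion_screen(if (length(normal_rho) == 1L) normal_rho else NA_real_)

  out <- structure(
    list(per_minute = per_minute, summary = summary, rho_curves = curves,
         inclusion = inclusion, qc = qc),
    class = "fpm_analysis"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(per_minute, file.path(out_dir, "per_minute_metrics.csv"))
    readr::write_csv(as_tibble(summary), file.path(out_dir, "period_summary.csv"))
    readr::write_csv(curves, file.path(out_dir, "rho_curves.csv"))
    write_json(list(inclusion = inclusion, dropped_candidates = qc),
               file.path(out_dir, "qc_report.json"),
               dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.fpm_analysis <- function(x, ...) {
  cat("<fpm_analysis>\n")
  print(as_tibble(x$summary))
  invisible(x)
}

#' Group-level direct-effect and after-effect comparisons
#'
#' For each group, compares each participant's period mean of each metric
#' between Normal and Force periods (direct effect) and between Normal
#' and Transparent periods (after-effect) with two-sided Wilcoxon
#' signed-rank tests. The primary contrast is step-start paretic
#' rho_disp, tested at `alpha` (0.025: two primary comparisons per
#' group); secondary metrics are reported with raw p-values at the same
#' threshold and flagged as secondary.
#'
#' @param summaries Named list of [period_summary()] tibbles, one per
#'   participant.
#' @param groups Named character vector mapping participant names to
#'   group labels.
#' @param alpha Significance threshold (default 0.025).
#' @param metrics Metric columns to compare (present in the summaries).
#' @param out_path Optional JSON output path.
#' @return Tibble with one row per group, contrast, metric and side:
#'   statistic, p-value, significance flag, Cohen's d of the paired
#'   differences, n, and a `primary` flag.
#' @export
run_group_study <- function(summaries, groups, alpha = 0.025,
                            metrics = c("rho_start", "rho_end",
                                        "mean_step_width_m",
                                        "mean_step_length_m",
                                        "mean_foot_placement_m"),
                            out_path = NULL) {
  if (is.null(names(summaries)) || is.null(names(groups))) {
    abort("`summaries` and `groups` must be named by participant.")
  }
  missing_grp <- setdiff(names(summaries), names(groups))
  if (length(missing_grp) > 0L) {
    abort(paste0("No group assignment for: ", paste(missing_grp, collapse = ", ")))
  }
  long <- purrr::imap(summaries, function(s, id) {
    as_tibble(s) |> mutate(participant = id)
  }) |>
    list_rbind() |>
    mutate(group = unname(groups[.data$participant]))

  need <- c("Normal", "Force", "Transparent")
  bad <- long |>
    dplyr::distinct(.data$participant, .data$period, .data$side) |>
    dplyr::count(.data$participant, .data$side) |>
    dplyr::filter(.data$n < length(need))
  if (nrow(bad) > 0L) {
    abort(paste0("Participants missing protocol periods: ",
                 paste(unique(bad$participant), collapse = ", ")))
  }

  contrasts <- tibble(
    contrast = c("direct effect", "after-effect"),
    period_b = c("Force", "Transparent")
  )
  grid <- tidyr::expand_grid(
    group = unique(long$group),
    contrast = contrasts$contrast,
    metric = metrics,
    side = c("paretic", "nonparetic")
  ) |>
    dplyr::left_join(contrasts, by = "contrast")

  res <- purrr::pmap(grid, function(group, contrast, metric, side, period_b) {
    sub <- long[long$group == group & long$side == side, ]
    wide <- sub |>
      select("participant", "period", dplyr::all_of(metric)) |>
      pivot_wider(names_from = "period", values_from = dplyr::all_of(metric))
    cmp <- paired_compare(wide$Normal, wide[[period_b]], alpha = alpha,
                          contrast = paste(group, contrast, side, metric))
    tidy(cmp) |>
      select(-"contrast") |>
      mutate(group = group, contrast = contrast, metric = metric, side = side,
             primary = metric == "rho_start" & side == "paretic")
  }) |>
    list_rbind() |>
    select("group", "contrast", "metric", "side", "primary", "statistic",
           "p_value", "alpha", "significant", "effect_size_d", "n")

  if (!is.null(out_path)) {
    write_json(res, out_path, dataframe = "rows", auto_unbox = TRUE,
               digits = NA, na = "null")
  }
  res
}
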