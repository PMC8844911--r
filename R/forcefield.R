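#' Force-field coefficient schedule
#'
#' The controller targets a step width `SW = A * x_pelvis + B * SW_mean`
#' (see [target_step_width()]) with coefficients `A`, `B` that depend on
#' walking speed. A schedule stores the assistive and perturbing
#' coefficient sets on a speed grid (0.2 to 1.2 m/s by default); values
#' between grid points are linearly interpolated and speeds outside the
#' grid are clamped to the nearest end.
#'
#' @param speeds Strictly increasing speed grid in m/s.
#' @param assist_A,assist_B,perturb_A,perturb_B Coefficient values on the
#'   grid (recycled if scalar).
#' @return A `coefficient_schedule` object.
#' @export
coefficient_schedule <- function(speeds = c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2),
                                 assist_A, assist_B, perturb_A, perturb_B) {
  k <- length(speeds)
  if (k < 2L || any(diff(speeds) <= 0)) abort("`speeds` must be strictly increasing, length >= 2.")
  rec <- function(v, nm) {
    if (length(v) == 1L) v <- rep(v, k)
    if (length(v) != k) abort(paste0("`", nm, "` must have length 1 or length(speeds)."))
    v
  }
  structure(
    list(speeds = as.numeric(speeds),
         assist = list(A = rec(assist_A, "assist_A"), B = rec(assist_B, "assist_B")),
         perturb = list(A = rec(perturb_A, "perturb_A"), B = rec(perturb_B, "perturb_B"))),
    class = "coefficient_schedule"
  )
}

#' Illustrative default coefficient schedule
#'
#' The published speed-dependent best-fit coefficients are not reproduced
#' here; this schedule is an illustrative stand-in with the qualitative
#' structure the controller modes require — assistive `A > 0` (push the
#' swing leg with the pelvis state), perturbing `A < 0` (push against it),
#' `B = 1` at all speeds — intended for simulation and tests only.
#'
#' @return A `coefficient_schedule`.
#' @export
default_schedule <- function() {
  coefficient_schedule(
    speeds = c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2),
    assist_A = c(1.5, 1.4, 1.3, 1.2, 1.1, 1.0),
    assist_B = 1,
    perturb_A = -c(1.5, 1.4, 1.3, 1.2, 1.1, 1.0),
    perturb_B = 1
  )
}

#' Read / write a coefficient schedule as JSON
#'
#' Schema: `{"speeds": [...], "assist": {"A": [...], "B": [...]},
#' "perturb": {"A": [...], "B": [...]}}`.
#'
#' @param path JSON file path.
#' @return [read_schedule_json()] returns a `coefficient_schedule`;
#'   [write_schedule_json()] returns `path` invisibly.
#' @export
read_schedule_json <- function(path) {
  j <- read_json(path, simplifyVector = TRUE)
  coefficient_schedule(j$speeds, j$assist$A, j$assist$B, j$perturb$A, j$perturb$B)
}

#' @rdname read_schedule_json
#' @param schedule A `coefficient_schedule`.
#' @export
write_schedule_json <- function(schedule, path) {
  write_json(unclass(schedule), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Interpolate controller coefficients at a walking speed
#'
#' Linear interpolation on the schedule's speed grid; speeds below the
#' lowest grid point use that grid point's coefficients (and likewise
#' above the top of the grid).
#'
#' @param schedule A `coefficient_schedule`.
#' @param mode `"assistive"` or `"perturbing"`.
#' @param speed Walking speed in m/s.
#' @return Named numeric vector `c(A = ..., B = ...)`.
#' @export
interpolate_coefficients <- function(schedule, mode = c("assistive", "perturbing"),
                                     speed) {
  mode <- match.arg(mode)
  set <- if (mode == "assistive") schedule$assist else schedule$perturb
  s <- min(max(speed, schedule$speeds[1L]), schedule$speeds[length(schedule$speeds)])
  c(A = approx(schedule$speeds, set$A, xout = s)$y,
    B = approx(schedule$speeds, set$B, xout = s)$y)
}

#' Controller target step width
#'
#' `SW = A * x_pelvis + B * SW_mean`, where `x_pelvis` is the mediolateral
#' position of the sacrum relative to the stance heel at the step start
#' (signed toward the swing side, shared with [pelvis_state_curve()] point
#' 0) and `SW_mean` is the participant's mean step width from the last 50
#' steps of the baseline normal-walking trial.
#'
#' @param A,B Coefficients (see [interpolate_coefficients()]).
#' @param x_pelvis Pelvis displacement at step start (m).
#' @param sw_mean Baseline mean step width (m).
#' @return Target step width in meters.
#' @export
target_step_width <- function(A, B, x_pelvis, sw_mean) {
  A * x_pelvis + B * sw_mean
}

#' Spring force toward a mediolateral target
#'
#' The force-field renders a virtual spring between the swing leg and its
#' targeted mediolateral location: `F = stiffness * (target - actual)`,
#' positive toward the target, with an effective stiffness of 180 N/m.
#'
#' @param target_m,actual_m Target and actual leg positions in the shared
#'   mediolateral frame (m).
#' @param stiffness_npm Spring stiffness in N/m (default 180).
#' @return Force in Newtons (signed toward the target).
#' @export
spring_force <- function(target_m, actual_m, stiffness_npm = 180) {
  stiffness_npm * (target_m - actual_m)
}

#' Per-step controller output for a given mode
#'
#' In transparent mode the wires track the leg, so the target equals the
#' actual position and the net force is zero by construction. Assistive
#' and perturbing modes compute the target from the control equation with
#' that mode's speed-interpolated coefficients and apply the spring law.
#'
#' @param mode `"transparent"`, `"assistive"`, or `"perturbing"`.
#' @param x_pelvis Pelvis displacement at step start (m, signed convention).
#' @param speed Walking speed in m/s.
#' @param schedule A `coefficient_schedule`.
#' @param sw_mean Baseline mean step width (m).
#' @param actual_m Actual mediolateral leg position (m).
#' @param stiffness_npm Spring stiffness (default 180 N/m).
#' @return List with `target_m` and `force_n`.
#' @export
mode_target <- function(mode, x_pelvis, speed, schedule, sw_mean, actual_m,
                        stiffness_npm = 180) {
  if (!mode %in% c("transparent", "assistive", "perturbing")) {
    abort(paste0("Unknown force-field mode: ", mode))
  }
  if (mode == "transparent") {
    return(list(target_m = actual_m, force_n = 0))
  }
  ab <- interpolate_coefficients(schedule, mode, speed)
  target <- target_step_width(ab[["A"]], ab[["B"]], x_pelvis, sw_mean)
  list(target_m = target,
       force_n = spring_force(target, actual_m, stiffness_npm))
}
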