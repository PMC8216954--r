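# Speed-sensitivity analysis of the REM: density as a function of the
# average-speed parameter at fixed trap rate and detection zone, and the
# effect of fixed absolute speed perturbations.

#' Density-versus-speed sensitivity curve
#'
#' Evaluates the REM density across a speed grid with the trap rate and
#' detection zone held fixed. Because D is proportional to 1/v the curve
#' is convex and D(v) * v is constant along it: a fixed absolute error in
#' speed distorts the estimate far more for slow-moving species.
#'
#' @param rate Trap rate, events per camera-day.
#' @param zone A [detection_zone()].
#' @param speeds Speed grid, km/h (all > 0).
#' @return Object of class `sensitivity_curve`: data frame `speed` (km/h)
#'   and `density` (individuals per 10 km^2), with the fixed inputs
#'   attached.
#' @export
density_speed_curve <- function(rate, zone, speeds) {
  if (any(speeds <= 0)) stop("all speeds must be > 0", call. = FALSE)
  speeds <- as.numeric(speeds)
  dens <- 10 * rem_density(rate, speeds, zone)
  structure(data.frame(speed = speeds, density = dens),
            fixed_inputs = list(rate = rate, zone = zone),
            class = c("sensitivity_curve", "data.frame"))
}

#' Effect of an absolute speed perturbation on REM density
#'
#' Exact (not linearised) change in density when the speed moves from
#' `v0` to `v0 + delta_v` with everything else fixed. `delta_d` is
#' reported as the decrease `d0 - d1`, positive when speed increases.
#'
#' @param rate Trap rate, events per camera-day.
#' @param zone A [detection_zone()].
#' @param v0 Baseline speed, km/h (> 0).
#' @param delta_v Absolute speed change, km/h (`v0 + delta_v > 0`).
#' @return Object of class `perturbation_result`: `v0`, `delta_v`, `d0`,
#'   `d1`, `delta_d` (all densities in individuals per 10 km^2).
#' @export
perturbation_effect <- function(rate, zone, v0, delta_v) {
  if (v0 <= 0 || v0 + delta_v <= 0)
    stop("v0 and v0 + delta_v must be > 0", call. = FALSE)
  d0 <- 10 * rem_density(rate, v0, zone)
  d1 <- 10 * rem_density(rate, v0 + delta_v, zone)
  structure(list(v0 = v0, delta_v = delta_v, d0 = d0, d1 = d1,
                 delta_d = d0 - d1, rate = rate, zone = zone),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("speed %.3g -> %.3g km/h: density %.3f -> %.3f, change %.4g individuals/10 km^2\n",
              x$v0, x$v0 + x$delta_v, x$d0, x$d1, x$delta_d))
  invisible(x)
}

#' Ratio of slow- to fast-species sensitivity
#'
#' For a shared absolute perturbation delta and shared fixed inputs,
#' `|delta_d_slow| / |delta_d_fast|`, which reduces to the closed form
#' `(v_fast * (v_fast + delta)) / (v_slow * (v_slow + delta))` and tends
#' to `(v_fast / v_slow)^2` as delta -> 0.
#'
#' @param result_slow,result_fast [perturbation_effect()] results sharing
#'   `delta_v`, `rate` and zone.
#' @return The unitless sensitivity ratio.
#' @export
sensitivity_ratio <- function(result_slow, result_fast) {
  stopifnot(inherits(result_slow, "perturbation_result"),
            inherits(result_fast, "perturbation_result"))
  if (abs(result_slow$delta_v - result_fast$delta_v) > 1e-12 ||
      abs(result_slow$rate - result_fast$rate) > 1e-12)
    stop("results must share delta_v and the fixed inputs", call. = FALSE)
  if (result_fast$delta_d == 0)
    stop("fast-species effect is zero", call. = FALSE)
  abs(result_slow$delta_d) / abs(result_fast$delta_d)
}
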