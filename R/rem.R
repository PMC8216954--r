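# Random encounter model: event building, trap rates, the density
# equation D = (y/t) * pi / (v * r * (2 + theta)), bootstrap trap-rate
# variance and delta-method propagation.

#' Camera detection zone
#'
#' Sector-shaped zone in front of a camera: radius `radius_r` (km) and
#' arc `arc_theta` (radians), each with a standard error so detection-zone
#' uncertainty can be propagated into density estimates.
#'
#' @param radius_r Zone radius, km (e.g. 11.6 m = 0.0116 km).
#' @param arc_theta Zone arc, radians (0 < theta < 2*pi).
#' @param radius_se,arc_se Standard errors (same units).
#' @return Object of class `rem_detection_zone`.
#' @export
detection_zone <- function(radius_r, arc_theta, radius_se = 0, arc_se = 0) {
  if (radius_r <= 0) stop("radius_r must be > 0", call. = FALSE)
  if (arc_theta <= 0 || arc_theta >= 2 * pi)
    stop("arc_theta must be in (0, 2*pi)", call. = FALSE)
  if (radius_se < 0 || arc_se < 0) stop("standard errors must be >= 0", call. = FALSE)
  structure(list(radius_r = radius_r, radius_se = radius_se,
                 arc_theta = arc_theta, arc_se = arc_se),
            class = "rem_detection_zone")
}

#' @export
print.rem_detection_zone <- function(x, ...) {
  cat(sprintf("detection zone: r = %.4g km (SE %.3g), theta = %.4g rad (SE %.3g)\n",
              x$radius_r, x$radius_se, x$arc_theta, x$arc_se))
  invisible(x)
}

time_minutes <- function(t) {
  if (inherits(t, "POSIXct")) as.numeric(t) / 60 else as.numeric(t)
}

#' Merge photo records into independent events
#'
#' Per camera, photos are merged into one event while the gap between
#' consecutive photos is at most `event_gap` minutes; a return strictly
#' more than `event_gap` minutes later starts a new event. Bursts of
#' consecutive trigger pictures therefore collapse into a single event.
#' If `deployments` is given, records outside a camera's deployment
#' window are excluded with a message reporting the count.
#'
#' @param records Data frame with `camera_id` and `timestamp` (POSIXct,
#'   or numeric minutes for synthetic data).
#' @param event_gap Gap threshold in minutes (default 10; the new-event
#'   rule is strict `> event_gap`).
#' @param deployments Optional data frame `camera_id`, `start`, `end`.
#' @return Data frame of events: `camera_id`, `start`, `end`, `n_photos`.
#' @export
build_events <- function(records, event_gap = 10, deployments = NULL) {
  stopifnot(all(c("camera_id", "timestamp") %in% names(records)))
  if (!is.null(deployments)) {
    m <- match(records$camera_id, deployments$camera_id)
    ok <- !is.na(m) & records$timestamp >= deployments$start[m] &
      records$timestamp < deployments$end[m]
    n_out <- sum(!ok)
    if (n_out > 0)
      message(n_out, " record(s) outside deployment windows excluded")
    records <- records[ok, , drop = FALSE]
  }
  if (!nrow(records))
    return(data.frame(camera_id = character(0), start = records$timestamp[0],
                      end = records$timestamp[0], n_photos = integer(0)))
  o <- order(records$camera_id, records$timestamp)
  records <- records[o, , drop = FALSE]
  tm <- time_minutes(records$timestamp)
  newev <- c(TRUE, records$camera_id[-1] != records$camera_id[-nrow(records)] |
               diff(tm) > event_gap * (1 + 1e-9))
  ev <- cumsum(newev)
  first <- which(newev)
  last <- c(first[-1] - 1L, nrow(records))
  data.frame(camera_id = records$camera_id[first],
             start = records$timestamp[first],
             end = records$timestamp[last],
             n_photos = as.integer(tabulate(ev)),
             row.names = NULL)
}

events_per_camera <- function(events, efforts) {
  y <- table(factor(events$camera_id, levels = efforts$camera_id))
  as.numeric(y)
}

#' Pooled camera-trap rate
#'
#' Point estimate of the encounter rate y/t: total events divided by total
#' effort (`method = "pooled"`, default), or the unweighted mean of
#' per-camera rates (`method = "mean"`).
#'
#' @param events Event data frame (see [build_events()]) whose
#'   `camera_id`s all appear in `efforts`.
#' @param efforts Data frame with `camera_id` and `active_days`
#'   (camera-days, > 0).
#' @param method `"pooled"` or `"mean"`.
#' @return Trap rate in events per camera-day.
#' @export
trap_rate <- function(events, efforts, method = c("pooled", "mean")) {
  method <- match.arg(method)
  stopifnot(all(c("camera_id", "active_days") %in% names(efforts)))
  if (any(efforts$active_days <= 0))
    stop("all active_days must be > 0", call. = FALSE)
  if (nrow(events) && !all(events$camera_id %in% efforts$camera_id))
    stop("events reference cameras missing from the effort table", call. = FALSE)
  tt <- sum(efforts$active_days)
  if (tt <= 0) stop("total effort is zero", call. = FALSE)
  y <- events_per_camera(events, efforts)
  if (method == "pooled") sum(y) / tt else mean(y / efforts$active_days)
}

#' REM density from a trap rate
#'
#' The ideal-gas encounter equation: with the trap rate converted to
#' events per hour, `D = rate * pi / (v * r * (2 + theta))`, giving
#' individuals per km^2 when `v` is km/h and `r` km.
#'
#' @param rate Trap rate in events per camera-day.
#' @param v Average movement speed, km/h (> 0).
#' @param zone A [detection_zone()].
#' @return Density in individuals per km^2 (multiply by 10 for the
#'   conventional individuals per 10 km^2 reporting scale).
#' @export
rem_density <- function(rate, v, zone) {
  stopifnot(inherits(zone, "rem_detection_zone"))
  if (any(v <= 0)) stop("v must be > 0", call. = FALSE)
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  rate_h <- rate / 24
  rate_h * pi / (v * zone$radius_r * (2 + zone$arc_theta))
}

#' Bootstrap the trap rate over camera locations
#'
#' Nonparametric bootstrap: each iteration resamples whole cameras (their
#' event count and effort) with replacement and recomputes the rate.
#'
#' @inheritParams trap_rate
#' @param n_iterations Bootstrap iterations (default 10,000; values below
#'   100 warn).
#' @param seed RNG seed.
#' @param method Rate estimator passed through to [trap_rate()] logic.
#' @return Object of class `trap_rate_estimate`: `rate` (point estimate on
#'   the full data), `boot_mean`, `boot_sd`, `boot_quantiles` (2.5/97.5%),
#'   `draws`, `n_iterations`, `seed`. Units: events per camera-day.
#' @export
bootstrap_trap_rate <- function(events, efforts, n_iterations = 10000,
                                seed = 1L, method = c("pooled", "mean")) {
  method <- match.arg(method)
  if (nrow(efforts) < 2) stop("need at least 2 cameras to bootstrap", call. = FALSE)
  if (n_iterations < 100) warning("fewer than 100 bootstrap iterations")
  y <- events_per_camera(events, efforts)
  t <- efforts$active_days
  n <- length(y)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_iterations, replace = TRUE), n_iterations, n)
  ys <- matrix(y[idx], n_iterations, n)
  ts <- matrix(t[idx], n_iterations, n)
  draws <- if (method == "pooled") rowSums(ys) / rowSums(ts)
           else rowMeans(ys / ts)
  structure(list(rate = trap_rate(events, efforts, method),
                 boot_mean = mean(draws), boot_sd = sd(draws),
                 boot_quantiles = quantile(draws, c(0.025, 0.975), names = FALSE),
                 draws = draws, n_iterations = n_iterations,
                 seed = seed, method = method),
            class = "trap_rate_estimate")
}

#' @export
print.trap_rate_estimate <- function(x, ...) {
  cat(sprintf("trap rate: %.4g ev/camera-day (bootstrap mean %.4g, SD %.4g, 95%% [%.4g, %.4g], %d iterations, %s)\n",
              x$rate, x$boot_mean, x$boot_sd,
              x$boot_quantiles[1], x$boot_quantiles[2], x$n_iterations, x$method))
  invisible(x)
}

#' REM density with delta-method uncertainty
#'
#' Point density from [rem_density()]; squared CV by the delta method,
#' `CV^2(D) = CV^2(y/t) + CV^2(v) + CV^2(r) + Var(theta)/(2+theta)^2`;
#' and a 95% interval from a resampling distribution that combines the
#' trap-rate bootstrap draws (or normal draws if only an SD is given)
#' with independent zero-truncated normal draws of v, r and theta.
#' Set `include_param_uncertainty = FALSE` for a trap-rate-only interval.
#'
#' @param rate A `trap_rate_estimate` from [bootstrap_trap_rate()], or a
#'   plain rate (events/camera-day) combined with `rate_sd`.
#' @param v,v_se Average speed (km/h) and its standard error.
#' @param zone A [detection_zone()] carrying `radius_se` and `arc_se`.
#' @param rate_sd SD of the trap rate when `rate` is a plain number.
#' @param n_draws Resampling draws for the interval.
#' @param seed RNG seed for the parametric draws.
#' @param include_param_uncertainty Include v/r/theta draws in the CI.
#' @return Object of class `rem_estimate` with `density` (per km^2),
#'   `density_per_10km2`, `cv` (fraction), `ci` (per 10 km^2), and the
#'   inputs used.
#' @export
rem_variance <- function(rate, v, v_se, zone, rate_sd = NULL,
                         n_draws = 10000, seed = 1L,
                         include_param_uncertainty = TRUE) {
  stopifnot(inherits(zone, "rem_detection_zone"))
  if (v_se < 0) stop("v_se must be >= 0", call. = FALSE)
  if (inherits(rate, "trap_rate_estimate")) {
    rate_draws <- rate$draws
    rate_sd <- rate$boot_sd
    rate_pt <- rate$rate
  } else {
    if (is.null(rate_sd)) rate_sd <- 0
    rate_pt <- rate
    rate_draws <- NULL
  }
  d_pt <- rem_density(rate_pt, v, zone)
  cv2 <- (if (rate_pt > 0) (rate_sd / rate_pt)^2 else 0) + (v_se / v)^2 +
    (zone$radius_se / zone$radius_r)^2 +
    zone$arc_se^2 / (2 + zone$arc_theta)^2
  cv <- sqrt(cv2)
  set.seed(seed)
  if (is.null(rate_draws)) {
    rate_draws <- if (rate_sd > 0) pmax(rnorm(n_draws, rate_pt, rate_sd), 0)
                  else rep(rate_pt, n_draws)
  } else if (length(rate_draws) != n_draws) {
    rate_draws <- sample(rate_draws, n_draws, replace = TRUE)
  }
  trunc0 <- function(m, s, n) if (s > 0) pmax(rnorm(n, m, s), 1e-12) else rep(m, n)
  if (include_param_uncertainty) {
    vd <- trunc0(v, v_se, n_draws)
    rd <- trunc0(zone$radius_r, zone$radius_se, n_draws)
    thd <- trunc0(zone$arc_theta, zone$arc_se, n_draws)
  } else {
    vd <- rep(v, n_draws); rd <- rep(zone$radius_r, n_draws)
    thd <- rep(zone$arc_theta, n_draws)
  }
  dd <- (rate_draws / 24) * pi / (vd * rd * (2 + thd))
  ci <- quantile(dd, c(0.025, 0.975), names = FALSE) * 10
  structure(list(density = d_pt, density_per_10km2 = 10 * d_pt,
                 cv = cv, ci = ci,
                 inputs = list(rate = rate_pt, rate_sd = rate_sd, v = v,
                               v_se = v_se, zone = zone),
                 n_draws = n_draws, seed = seed,
                 include_param_uncertainty = include_param_uncertainty),
            class = "rem_estimate")
}

#' @export
print.rem_estimate <- function(x, ...) {
  cat(sprintf("REM density: %.3f individuals/10 km^2 (CV %.1f%%, 95%% CI [%.2f, %.2f])\n",
              x$density_per_10km2, 100 * x$cv, x$ci[1], x$ci[2]))
  cat(sprintf("  inputs: rate %.4g ev/cam-day, v %.3g km/h, r %.4g km, theta %.3g rad\n",
              x$inputs$rate, x$inputs$v, x$inputs$zone$radius_r,
              x$inputs$zone$arc_theta))
  invisible(x)
}

#' Correct a GPS-derived speed for fix-rate underestimation
#'
#' Coarse fix schedules hide path tortuosity, so telemetry speeds
#' underestimate true travel speed. Under the convention implemented
#' here, a stated underestimation fraction f means the observed speed is
#' (1 - f) of the true speed, so the corrected speed is `v / (1 - f)` and
#' the corresponding REM density shrinks by the factor (1 - f).
#'
#' @param v Observed average speed, km/h.
#' @param underestimation_fraction Fraction f in \[0, 1).
#' @return Corrected speed, km/h.
#' @export
apply_speed_correction <- function(v, underestimation_fraction) {
  if (underestimation_fraction < 0 || underestimation_fraction >= 1)
    stop("underestimation_fraction must be in [0, 1)", call. = FALSE)
  v / (1 - underestimation_fraction)
}
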