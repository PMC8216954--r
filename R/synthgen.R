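# Synthetic movement, camera-detection, hair-snag capture and GPS-fix
# generators. These emulate the statistical structure the estimators
# assume (ideal-gas / correlated-random-walk movement, sector-shaped
# detection zones, distance-decaying trap hazard) so every downstream
# module is testable without field data.

#' Define a rectangular simulation arena
#'
#' @param width,height Arena dimensions in km.
#' @param boundary `"reflect"` (closed park; default) or `"wrap"` (torus,
#'   useful for unbiased ideal-gas checks because it has no edge effects).
#' @return An object of class `rem_arena`.
#' @export
arena <- function(width, height, boundary = c("reflect", "wrap")) {
  boundary <- match.arg(boundary)
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0)
    stop("arena width and height must be positive numbers", call. = FALSE)
  structure(list(width = width, height = height, boundary = boundary),
            class = "rem_arena")
}

#' Correlated-random-walk movement parameters
#'
#' Step speeds are gamma-distributed with the given mean and SD; headings
#' persist with von Mises turning angles of concentration
#' `turn_concentration` (0 = uncorrelated, the ideal-gas regime; large =
#' nearly straight). The default step interval is chosen so that the mean
#' step length is one third of a camera detection radius, the contract the
#' discrete-position detector requires (step length << r).
#'
#' @param mean_speed Mean speed, km/h.
#' @param speed_sd SD of per-step speeds, km/h (0 = constant speed).
#' @param turn_concentration von Mises concentration of turning angles.
#' @param step_interval Time between native fixes, hours. Default
#'   `(zone_radius/3)/mean_speed`.
#' @param zone_radius Detection radius used to pick the default step, km.
#' @return An object of class `rem_movement_params`.
#' @export
movement_params <- function(mean_speed, speed_sd = 0, turn_concentration = 0,
                            step_interval = NULL, zone_radius = 0.0116) {
  if (mean_speed < 0) stop("mean_speed must be >= 0", call. = FALSE)
  if (speed_sd < 0) stop("speed_sd must be >= 0", call. = FALSE)
  if (turn_concentration < 0) stop("turn_concentration must be >= 0", call. = FALSE)
  if (is.null(step_interval)) {
    step_interval <- if (mean_speed > 0) (zone_radius / 3) / mean_speed else 0.05
  }
  if (step_interval <= 0) stop("step_interval must be > 0", call. = FALSE)
  structure(list(mean_speed = mean_speed, speed_sd = speed_sd,
                 turn_concentration = turn_concentration,
                 step_interval = step_interval),
            class = "rem_movement_params")
}

# von Mises sampler (Best & Fisher 1979 envelope-rejection).
rvonmises <- function(n, kappa) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    z <- cos(pi * runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- which(ok)
    if (length(k)) {
      th <- sign(runif(length(k)) - 0.5) * acos(pmin(1, pmax(-1, f[k])))
      out[(got + 1L):(got + length(k))] <- th
      got <- got + length(k)
    }
  }
  out
}

fold_reflect <- function(p, w) {
  p <- p %% (2 * w)
  ifelse(p > w, 2 * w - p, p)
}

#' Simulate correlated-random-walk movement paths
#'
#' Every animal starts at a uniform position with a uniform heading and
#' takes `floor(duration/step_interval)` steps; positions are reflected or
#' wrapped at the arena boundary according to `arena$boundary`.
#'
#' @param arena An [arena()].
#' @param n_animals Number of animals (>= 1).
#' @param params A [movement_params()].
#' @param duration Total tracking time, hours (>= one step interval).
#' @param seed Integer RNG seed; all draws are reproducible given it.
#' @return A `sim_paths` object: `time` (hours, length S+1), matrices `x`,
#'   `y` of dimension (S+1) x n_animals, plus the arena and parameters.
#' @export
simulate_movement <- function(arena, n_animals, params, duration, seed = 1L) {
  stopifnot(inherits(arena, "rem_arena"), inherits(params, "rem_movement_params"))
  if (n_animals < 1) stop("n_animals must be positive", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (duration < params$step_interval)
    stop("duration must be at least one step_interval", call. = FALSE)
  set.seed(seed)
  dt <- params$step_interval
  n_steps <- floor(duration / dt)
  W <- arena$width; H <- arena$height
  x <- matrix(0, n_steps + 1L, n_animals)
  y <- matrix(0, n_steps + 1L, n_animals)
  x[1L, ] <- runif(n_animals, 0, W)
  y[1L, ] <- runif(n_animals, 0, H)
  heading <- runif(n_animals, -pi, pi)
  mu <- params$mean_speed; sds <- params$speed_sd
  kap <- params$turn_concentration
  const_speed <- sds == 0 || mu == 0
  if (!const_speed) {
    shape <- mu^2 / sds^2
    rate <- mu / sds^2
  }
  wrap <- identical(arena$boundary, "wrap")
  for (s in seq_len(n_steps)) {
    heading <- heading + rvonmises(n_animals, kap)
    sp <- if (const_speed) rep(mu, n_animals) else rgamma(n_animals, shape, rate)
    nx <- x[s, ] + sp * dt * cos(heading)
    ny <- y[s, ] + sp * dt * sin(heading)
    if (wrap) {
      x[s + 1L, ] <- nx %% W
      y[s + 1L, ] <- ny %% H
    } else {
      x[s + 1L, ] <- fold_reflect(nx, W)
      y[s + 1L, ] <- fold_reflect(ny, H)
    }
  }
  structure(list(time = (0:n_steps) * dt, x = x, y = y,
                 arena = arena, params = params, seed = seed),
            class = "sim_paths")
}

#' @export
print.sim_paths <- function(x, ...) {
  cat(sprintf("sim_paths: %d animals, %d fixes each, dt = %.4g h, arena %g x %g km (%s)\n",
              ncol(x$x), nrow(x$x), x$params$step_interval,
              x$arena$width, x$arena$height, x$arena$boundary))
  invisible(x)
}

#' Extract one animal's path as a data frame
#'
#' @param paths A `sim_paths` object.
#' @param i Animal index.
#' @return Data frame with columns `animal_id`, `time` (h), `x`, `y` (km).
#' @export
get_path <- function(paths, i) {
  stopifnot(inherits(paths, "sim_paths"), i >= 1, i <= ncol(paths$x))
  data.frame(animal_id = paste0("A", i), time = paths$time,
             x = paths$x[, i], y = paths$y[, i])
}

#' Lay out a camera array
#'
#' Cameras at uniform random positions with uniform random headings and a
#' shared detection zone. Supply your own data frame to
#' [detect_camera_events()] for full control.
#'
#' @param n Number of cameras.
#' @param arena An [arena()].
#' @param zone A [detection_zone()].
#' @param seed RNG seed.
#' @return Data frame: `camera_id`, `x`, `y`, `heading`, `r`, `theta`.
#' @export
camera_array <- function(n, arena, zone, seed = 1L) {
  stopifnot(inherits(arena, "rem_arena"), inherits(zone, "rem_detection_zone"))
  set.seed(seed)
  data.frame(camera_id = sprintf("C%03d", seq_len(n)),
             x = runif(n, 0, arena$width), y = runif(n, 0, arena$height),
             heading = runif(n, -pi, pi),
             r = zone$radius_r, theta = zone$arc_theta)
}

#' Sector membership test for camera detection zones
#'
#' A point is inside the zone when its distance to the camera is at most
#' `radius` and its bearing from the camera lies within `theta/2` of the
#' camera heading. The camera position itself counts as inside.
#'
#' @param px,py Point coordinates, km (vectorised).
#' @param cx,cy Camera position, km.
#' @param heading Camera facing direction, radians.
#' @param radius Zone radius, km.
#' @param theta Zone arc, radians.
#' @return Logical vector.
#' @export
point_in_sector <- function(px, py, cx, cy, heading, radius, theta) {
  dx <- px - cx; dy <- py - cy
  d2 <- dx * dx + dy * dy
  ang <- atan2(dy, dx)
  dh <- (ang - heading + pi) %% (2 * pi) - pi
  (d2 <= radius^2) & (abs(dh) <= theta / 2 | d2 == 0)
}

#' Detect camera-trap events on simulated paths
#'
#' Each fix falling inside a camera's sector produces a raw detection;
#' consecutive in-zone fixes and returns of the same animal to the same
#' camera within `event_gap` minutes are merged into one event, mirroring
#' the event rule applied to real photo records. The simulator's contract
#' requires the movement step length to be well below the zone radius so
#' passes are not skipped over.
#'
#' @param paths A `sim_paths` object.
#' @param cameras Data frame with columns `camera_id`, `x`, `y`,
#'   `heading`, `r`, `theta` (e.g. from [camera_array()]).
#' @param event_gap Gap (minutes) beyond which a return is a new event.
#' @return Data frame of events: `camera_id`, `animal_id`, `start`, `end`
#'   (hours on the simulation clock), `n_fixes`.
#' @export
detect_camera_events <- function(paths, cameras, event_gap = 10) {
  stopifnot(inherits(paths, "sim_paths"))
  need <- c("camera_id", "x", "y", "heading", "r", "theta")
  if (!all(need %in% names(cameras)))
    stop("cameras must have columns ", paste(need, collapse = ", "), call. = FALSE)
  W <- paths$arena$width; H <- paths$arena$height
  if (any(cameras$x < 0 | cameras$x > W | cameras$y < 0 | cameras$y > H))
    warning("some cameras lie outside the arena")
  S <- nrow(paths$x)
  px <- as.vector(paths$x); py <- as.vector(paths$y)
  ord <- order(px)
  sx <- px[ord]
  hits <- vector("list", nrow(cameras))
  for (ci in seq_len(nrow(cameras))) {
    cx <- cameras$x[ci]; cy <- cameras$y[ci]
    r <- cameras$r[ci]
    rng <- findInterval(c(cx - r, cx + r), sx)
    if (rng[2] <= rng[1]) next
    cand <- ord[(rng[1] + 1L):rng[2]]
    cand <- cand[abs(py[cand] - cy) <= r]
    if (!length(cand)) next
    inz <- point_in_sector(px[cand], py[cand], cx, cy,
                           cameras$heading[ci], r, cameras$theta[ci])
    cand <- cand[inz]
    if (!length(cand)) next
    hits[[ci]] <- data.frame(camera = ci,
                             animal = (cand - 1L) %/% S + 1L,
                             t = paths$time[(cand - 1L) %% S + 1L])
  }
  hits <- do.call(rbind, hits)
  empty <- data.frame(camera_id = character(0), animal_id = character(0),
                      start = numeric(0), end = numeric(0), n_fixes = integer(0))
  if (is.null(hits) || !nrow(hits)) return(empty)
  hits <- hits[order(hits$camera, hits$animal, hits$t), ]
  # relative epsilon so consecutive fixes on a computed time grid are
  # never split by one-ulp jitter in diff()
  gap_h <- event_gap / 60 * (1 + 1e-9)
  newev <- c(TRUE, diff(hits$camera) != 0 | diff(hits$animal) != 0 |
               diff(hits$t) > gap_h)
  ev <- cumsum(newev)
  data.frame(camera_id = cameras$camera_id[hits$camera[newev]],
             animal_id = paste0("A", hits$animal[newev]),
             start = tapply(hits$t, ev, min)[],
             end = tapply(hits$t, ev, max)[],
             n_fixes = as.integer(tabulate(ev)),
             row.names = NULL)
}

#' Simulation truth for hair-snag capture histories
#'
#' Defaults are the reference analysis point estimates: density 0.287
#' bears/km^2, g0 = 0.59, sigma = 0.74 km, detection-shape theta = 0.75,
#' 5 weekly occasions, 31% males.
#'
#' @param true_density Individuals per km^2.
#' @param g0 Baseline detection probability at distance zero (0 < g0 < 1).
#' @param sigma Spatial scale of the detection kernel, km.
#' @param theta_det Kernel shape in \[0.5, 1\] (0.5 exponential, 1 Gaussian).
#' @param n_occasions Sampling occasions (weeks).
#' @param sex_ratio_male Probability an individual is male.
#' @param behavioral_effect Log-hazard offset applied after an
#'   individual's first capture at any trap (0 = none).
#' @return An object of class `scr_sim_config`.
#' @export
scr_sim_config <- function(true_density = 0.287, g0 = 0.59, sigma = 0.74,
                           theta_det = 0.75, n_occasions = 5,
                           sex_ratio_male = 0.31, behavioral_effect = 0) {
  if (g0 < 0 || g0 >= 1) stop("g0 must be in [0, 1)", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (theta_det < 0.5 || theta_det > 1)
    stop("theta_det must be in [0.5, 1]", call. = FALSE)
  if (n_occasions < 1) stop("n_occasions must be >= 1", call. = FALSE)
  structure(list(true_density = true_density, g0 = g0, sigma = sigma,
                 theta_det = theta_det, n_occasions = as.integer(n_occasions),
                 sex_ratio_male = sex_ratio_male,
                 behavioral_effect = behavioral_effect),
            class = "scr_sim_config")
}

#' Simulate a hair-snag capture history
#'
#' Activity centers are uniform over the extent with expected count
#' `true_density * area` (Poisson). Detection of individual i at trap j on
#' an occasion is Bernoulli with the complementary log-log hazard form
#' used by the SCR estimator; the behavioural offset switches on after the
#' first capture at any trap. Individuals never captured are absent from
#' the returned history; the simulation truth (realised N, centers) is
#' attached as `attr(, "truth")`.
#'
#' @param cfg An [scr_sim_config()].
#' @param traps Data frame with `trap_id`, `x`, `y` (km).
#' @param extent Extent over which centers live: a [state_space()] (its
#'   bounding box is used), an [arena()], or `c(xmin, xmax, ymin, ymax)`.
#' @param seed RNG seed.
#' @return A [capture_history()] with truth attached.
#' @export
simulate_scr_captures <- function(cfg, traps, extent, seed = 1L) {
  stopifnot(inherits(cfg, "scr_sim_config"))
  if (!nrow(traps)) stop("traps must be non-empty", call. = FALSE)
  bb <- extent_bbox(extent)
  set.seed(seed)
  area <- (bb[2] - bb[1]) * (bb[4] - bb[3])
  N <- rpois(1L, cfg$true_density * area)
  J <- nrow(traps); K <- cfg$n_occasions
  alpha0 <- if (cfg$g0 == 0) -Inf else g0_to_alpha0(cfg$g0)
  sex <- rbinom(N, 1L, cfg$sex_ratio_male)
  cx <- runif(N, bb[1], bb[2]); cy <- runif(N, bb[3], bb[4])
  if (N == 0L) {
    hist <- capture_history(data.frame(individual_id = character(0),
                                       trap_id = character(0),
                                       occasion = integer(0)),
                            sex = character(0), n_occasions = K,
                            trap_ids = as.character(traps$trap_id))
    attr(hist, "truth") <- list(N = 0L, area = area, centers = cbind(cx, cy),
                                sex = sex, cfg = cfg, bbox = bb)
    return(hist)
  }
  d2 <- outer(cx, traps$x, "-")^2 + outer(cy, traps$y, "-")^2
  kern <- exp(-(d2 / cfg$sigma^2)^cfg$theta_det)
  rows <- vector("list", N)
  for (i in seq_len(N)) {
    caught_before <- FALSE
    reci <- NULL
    for (k in seq_len(K)) {
      lh <- alpha0 + if (caught_before) cfg$behavioral_effect else 0
      p <- 1 - exp(-exp(lh) * kern[i, ])
      y <- runif(J) < p
      if (any(y)) {
        reci <- rbind(reci, cbind(which(y), k))
        caught_before <- TRUE
      }
    }
    if (!is.null(reci)) rows[[i]] <- cbind(i, reci)
  }
  rows <- do.call(rbind, rows)
  if (is.null(rows) || !nrow(rows)) {
    hist <- capture_history(data.frame(individual_id = character(0),
                                       trap_id = character(0),
                                       occasion = integer(0)),
                            n_occasions = K,
                            trap_ids = as.character(traps$trap_id))
    attr(hist, "truth") <- list(N = N, area = area, centers = cbind(cx, cy),
                                sex = sex, detected = integer(0), cfg = cfg,
                                bbox = bb)
    return(hist)
  }
  det_ids <- sort(unique(rows[, 1]))
  df <- data.frame(individual_id = paste0("ind", match(rows[, 1], det_ids)),
                   trap_id = as.character(traps$trap_id)[rows[, 2]],
                   occasion = as.integer(rows[, 3]))
  hist <- capture_history(df,
                          sex = ifelse(sex[det_ids] == 1L, "M", "F"),
                          n_occasions = K,
                          trap_ids = as.character(traps$trap_id))
  attr(hist, "truth") <- list(N = N, area = area, centers = cbind(cx, cy),
                              sex = sex, detected = det_ids, cfg = cfg, bbox = bb)
  hist
}

extent_bbox <- function(extent) {
  if (inherits(extent, "rem_arena"))
    return(c(0, extent$width, 0, extent$height))
  if (inherits(extent, "rem_state_space")) {
    g <- extent$grid
    hr <- extent$resolution / 2
    return(c(min(g[, 1]) - hr, max(g[, 1]) + hr, min(g[, 2]) - hr, max(g[, 2]) + hr))
  }
  if (is.numeric(extent) && length(extent) == 4L) return(extent)
  stop("extent must be an arena, a state_space, or c(xmin, xmax, ymin, ymax)",
       call. = FALSE)
}

#' Thin a movement path to a coarser GPS fix schedule
#'
#' Keeps the native fix nearest each requested time on a regular grid of
#' `interval` hours, optionally adding isotropic Gaussian position error.
#' This is the mechanism behind fix-rate speed bias: the straight line
#' between two retained fixes is never longer than the path between them.
#'
#' @param path Data frame with columns `time`, `x`, `y` (from
#'   [get_path()]) or any frame with those columns.
#' @param interval Desired fix interval, hours (>= the native interval).
#' @param jitter_sd SD of isotropic position noise, km.
#' @param seed RNG seed (only used when `jitter_sd > 0`).
#' @return Data frame with the same columns, thinned.
#' @export
sample_gps_fixes <- function(path, interval, jitter_sd = 0, seed = 1L) {
  stopifnot(all(c("time", "x", "y") %in% names(path)))
  tt <- path$time
  native <- median(diff(tt))
  if (interval < native * (1 - 1e-9))
    stop("interval must be at least the native fix interval", call. = FALSE)
  targets <- seq(tt[1], tt[length(tt)], by = interval)
  idx <- unique(pmin(length(tt), round((targets - tt[1]) / native) + 1L))
  out <- path[idx, , drop = FALSE]
  if (jitter_sd > 0) {
    set.seed(seed)
    out$x <- out$x + rnorm(nrow(out), 0, jitter_sd)
    out$y <- out$y + rnorm(nrow(out), 0, jitter_sd)
  }
  rownames(out) <- NULL
  out
}
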