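# Movement-speed estimation from GPS telemetry: per-segment speeds,
# seasonal and fix-interval filters, population averages, the log-scale
# one-factor variance decomposition, and fix-rate bias curves.

#' Per-segment movement speeds from GPS fixes
#'
#' One segment per consecutive fix pair within an animal: speed is the
#' Euclidean distance between the two relocations divided by the time
#' elapsed. Segments never span animals.
#'
#' @param fixes Data frame with `animal_id`, `timestamp` (POSIXct or
#'   numeric hours), `x`, `y` (planar km); an optional `population`
#'   column is carried through.
#' @return Data frame: `animal_id`, (`population`,) `t0` (segment start
#'   timestamp), `dt` (h), `distance` (km), `speed` (km/h).
#' @export
segment_speeds <- function(fixes) {
  stopifnot(all(c("animal_id", "timestamp", "x", "y") %in% names(fixes)))
  o <- order(fixes$animal_id, fixes$timestamp)
  fixes <- fixes[o, , drop = FALSE]
  n <- nrow(fixes)
  if (n < 2) stop("need at least 2 fixes", call. = FALSE)
  same <- fixes$animal_id[-1] == fixes$animal_id[-n]
  th <- if (inherits(fixes$timestamp, "POSIXct"))
    as.numeric(fixes$timestamp) / 3600 else as.numeric(fixes$timestamp)
  dt <- diff(th)
  if (any(same & dt <= 0)) {
    bad <- fixes$animal_id[-n][same & dt <= 0][1]
    stop("duplicate or non-increasing timestamps for animal ", bad, call. = FALSE)
  }
  keep <- which(same)
  dist <- sqrt(diff(fixes$x)^2 + diff(fixes$y)^2)[keep]
  out <- data.frame(animal_id = fixes$animal_id[keep],
                    t0 = fixes$timestamp[keep],
                    dt = dt[keep], distance = dist,
                    speed = dist / dt[keep])
  if ("population" %in% names(fixes))
    out$population <- fixes$population[keep]
  out
}

month_day <- function(t) {
  lt <- as.POSIXlt(t)
  (lt$mon + 1L) * 100L + lt$mday
}

#' Filter movement segments by season and fix interval
#'
#' Keeps segments starting inside the month-day window (inclusive both
#' ends) and with `dt <= max_dt` hours; the default 3-hour cap implements
#' a minimum fix rate of 8 locations/day. Counts removed by each filter
#' are reported with `message()` and attached as `attr(, "removed")`.
#'
#' @param segments Output of [segment_speeds()].
#' @param season `c("MM-DD", "MM-DD")` window applied to segment start
#'   timestamps (needs POSIXct timestamps), or `NULL` to skip.
#' @param max_dt Maximum segment duration in hours (`Inf` to skip).
#' @return Filtered segment data frame.
#' @export
filter_segments <- function(segments, season = c("07-01", "09-30"), max_dt = 3) {
  keep_season <- rep(TRUE, nrow(segments))
  if (!is.null(season)) {
    if (!inherits(segments$t0, "POSIXct"))
      stop("seasonal filtering needs POSIXct timestamps", call. = FALSE)
    code <- function(s) {
      p <- as.integer(strsplit(s, "-", fixed = TRUE)[[1]])
      p[1] * 100L + p[2]
    }
    md <- month_day(segments$t0)
    keep_season <- md >= code(season[1]) & md <= code(season[2])
  }
  keep_dt <- segments$dt <= max_dt
  removed <- c(season = sum(!keep_season), fix_interval = sum(keep_season & !keep_dt))
  message(sprintf("filter_segments: removed %d by season, %d by dt > %g h",
                  removed[1], removed[2], max_dt))
  out <- segments[keep_season & keep_dt, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Average movement speed of a population
#'
#' Arithmetic mean over segment speeds (pooled across animals), with SD
#' and SE = SD/sqrt(n).
#'
#' @param segments Output of [segment_speeds()] (possibly filtered).
#' @param population Optional label: subset to that population and stamp
#'   the estimate with it.
#' @return Object of class `speed_estimate`: `population`, `v_mean`,
#'   `v_sd`, `v_se` (km/h), `n_segments`.
#' @export
average_speed <- function(segments, population = NULL) {
  if (!is.null(population)) {
    segments <- segments[segments$population == population, , drop = FALSE]
  }
  if (!nrow(segments)) stop("no segments to average", call. = FALSE)
  v <- segments$speed
  structure(list(population = population %||% "all",
                 v_mean = mean(v), v_sd = sd(v),
                 v_se = sd(v) / sqrt(length(v)), n_segments = length(v)),
            class = "speed_estimate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.speed_estimate <- function(x, ...) {
  cat(sprintf("speed [%s]: %.3f +/- %.3f km/h (SE %.4f, n = %d segments)\n",
              x$population, x$v_mean, x$v_sd, x$v_se, x$n_segments))
  invisible(x)
}

#' Inter- vs intra-population variance in movement speed
#'
#' One-factor ANOVA of log(speed) on population identity. Zero speeds are
#' dropped (and counted) before the log transform. For a single balanced
#' factor the type III and sequential sums of squares coincide, so this
#' is fit with `lm`/`anova`. The factor share of the total sum of squares
#' is the interpopulation variation; the residual share is the
#' intrapopulation variation.
#'
#' @param segments Segment data frame with a `population` column.
#' @return Object of class `speed_anova`: `ss_between_pct`,
#'   `ss_within_pct`, `f_statistic`, `df` (numerator, denominator),
#'   `p_value`, `n_dropped_zero`, `n_used`.
#' @export
variance_decomposition <- function(segments) {
  stopifnot("population" %in% names(segments))
  pops <- unique(segments$population)
  if (length(pops) < 2) stop("need at least 2 populations", call. = FALSE)
  zero <- segments$speed <= 0
  n_zero <- sum(zero)
  seg <- segments[!zero, , drop = FALSE]
  cnt <- table(seg$population)
  if (length(cnt) < length(pops) || any(cnt < 2))
    stop("every population needs >= 2 segments with non-zero speed", call. = FALSE)
  fit <- lm(log(speed) ~ factor(population), data = seg)
  an <- anova(fit)
  ssb <- an$`Sum Sq`[1]; ssw <- an$`Sum Sq`[2]
  structure(list(ss_between_pct = 100 * ssb / (ssb + ssw),
                 ss_within_pct = 100 * ssw / (ssb + ssw),
                 f_statistic = an$`F value`[1],
                 df = c(an$Df[1], an$Df[2]),
                 p_value = an$`Pr(>F)`[1],
                 n_dropped_zero = n_zero, n_used = nrow(seg)),
            class = "speed_anova")
}

#' @export
print.speed_anova <- function(x, ...) {
  cat(sprintf("log-speed ANOVA: F(%d, %d) = %.2f, p = %.3g\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value))
  cat(sprintf("  between-population SS %.2f%%, within %.2f%% (%d zero speeds dropped)\n",
              x$ss_between_pct, x$ss_within_pct, x$n_dropped_zero))
  invisible(x)
}

#' Fix-rate bias curve for speed estimates
#'
#' Thins simulated paths to each requested fix interval with
#' [sample_gps_fixes()], recomputes the pooled mean segment speed, and
#' reports the percent underestimation relative to the finest interval.
#'
#' @param paths A `sim_paths` object from [simulate_movement()], or a
#'   list of path data frames (`time`, `x`, `y`).
#' @param intervals Fix intervals in hours; must include the native
#'   resolution (the finest interval is the reference).
#' @return Data frame: `interval`, `mean_speed` (km/h),
#'   `pct_underestimation` (%, 0 at the finest interval).
#' @export
fix_rate_bias_curve <- function(paths, intervals) {
  if (inherits(paths, "sim_paths")) {
    paths <- lapply(seq_len(ncol(paths$x)), function(i) get_path(paths, i))
  }
  intervals <- sort(intervals)
  native <- median(diff(paths[[1]]$time))
  if (intervals[1] > native * (1 + 1e-9))
    stop("intervals must include the native resolution", call. = FALSE)
  mean_speed_at <- function(interval) {
    tot_d <- 0; tot_n <- 0; tot_s <- 0
    for (p in paths) {
      q <- sample_gps_fixes(p, interval)
      if (nrow(q) < 2) next
      sp <- sqrt(diff(q$x)^2 + diff(q$y)^2) / diff(q$time)
      tot_s <- tot_s + sum(sp); tot_n <- tot_n + length(sp)
    }
    tot_s / tot_n
  }
  ms <- vapply(intervals, mean_speed_at, numeric(1))
  data.frame(interval = intervals, mean_speed = ms,
             pct_underestimation = 100 * (1 - ms / ms[1]))
}
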