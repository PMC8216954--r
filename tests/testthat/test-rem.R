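ts <- function(s) as.POSIXct(s, tz = "UTC")

test_that("photo bursts and returns merge into events by the 10-min rule", {
  rec <- data.frame(
    camera_id = c(rep("A", 3), "A", "A", "B", "B"),
    timestamp = ts(c("2015-07-01 10:00:00", "2015-07-01 10:00:02",
                     "2015-07-01 10:00:04",          # burst -> 1 event
                     "2015-07-01 12:00:00", "2015-07-01 12:11:00",  # 11 min -> 2
                     "2015-07-02 08:00:00", "2015-07-02 08:10:00"))) # exactly 10 -> 1
  ev <- build_events(rec, event_gap = 10)
  expect_equal(nrow(ev), 4)
  a <- ev[ev$camera_id == "A", ]
  expect_equal(nrow(a), 3)
  expect_equal(a$n_photos, c(3L, 1L, 1L))
  b <- ev[ev$camera_id == "B", ]
  expect_equal(nrow(b), 1)   # 10 min apart is still one event (rule is strict >)
  expect_equal(b$n_photos, 2L)
})

test_that("records outside deployment windows are excluded with a count", {
  rec <- data.frame(camera_id = c("A", "A"),
                    timestamp = ts(c("2015-07-01 10:00:00",
                                     "2015-09-20 10:00:00")))
  dep <- data.frame(camera_id = "A", start = ts("2015-07-01 00:00:00"),
                    end = ts("2015-09-01 00:00:00"))
  expect_message(ev <- build_events(rec, deployments = dep), "1 record")
  expect_equal(nrow(ev), 1)
})

test_that("trap rate is pooled events over pooled effort", {
  expect_equal(trap_rate(ref_events(), ref_efforts()), 67 / 2236)
  # zero events
  eff <- data.frame(camera_id = c("A", "B"), active_days = c(10, 20))
  none <- data.frame(camera_id = character(0))
  expect_equal(trap_rate(none, eff), 0)
  # doubling effort halves the rate
  ev <- data.frame(camera_id = c("A", "A", "B"))
  eff2 <- eff; eff2$active_days <- 2 * eff$active_days
  expect_equal(trap_rate(ev, eff2), trap_rate(ev, eff) / 2)
  expect_error(trap_rate(data.frame(camera_id = "Z"), eff), "missing")
})

test_that("rem_density reproduces the printed range and scales correctly", {
  zone <- detection_zone(0.0116, 0.698)
  rate <- 67 / 2236
  expect_equal(round(10 * rem_density(rate, 0.233, zone), 2), 5.38)
  expect_equal(round(10 * rem_density(rate, 0.309, zone), 2), 4.06)
  expect_equal(rem_density(0, 0.3, zone), 0)
  # D is homogeneous of degree -1 in v and r, strictly decreasing in theta
  expect_equal(rem_density(rate, 0.6, zone), rem_density(rate, 0.3, zone) / 2)
  zone2 <- detection_zone(2 * 0.0116, 0.698)
  expect_equal(rem_density(rate, 0.3, zone2), rem_density(rate, 0.3, zone) / 2)
  zone3 <- detection_zone(0.0116, 0.9)
  expect_lt(rem_density(rate, 0.3, zone3), rem_density(rate, 0.3, zone))
  expect_error(rem_density(rate, 0, zone), "v")
})

test_that("bootstrap matches exhaustive enumeration on a 3-camera toy set", {
  ev <- data.frame(camera_id = c("a", "a", "c", "c", "c", "c"))
  eff <- data.frame(camera_id = c("a", "b", "c"), active_days = c(10, 10, 10))
  # oracle: all 27 equally likely resamples enumerated directly
  y <- c(2, 0, 4)
  combos <- expand.grid(1:3, 1:3, 1:3)
  oracle_mean <- mean(apply(combos, 1, function(i) sum(y[i]) / 30))
  b <- bootstrap_trap_rate(ev, eff, n_iterations = 200000, seed = 1)
  expect_lt(abs(b$boot_mean - oracle_mean), 3 * b$boot_sd / sqrt(2e5))
  expect_equal(b$rate, 6 / 30)
})

test_that("degenerate and homogeneous bootstraps behave analytically", {
  # identical cameras -> zero bootstrap SD
  ev <- data.frame(camera_id = rep(c("a", "b", "c"), each = 2))
  eff <- data.frame(camera_id = c("a", "b", "c"), active_days = c(5, 5, 5))
  b <- bootstrap_trap_rate(ev, eff, n_iterations = 500, seed = 2)
  expect_equal(b$boot_sd, 0)
  # homogeneous array: bootstrap SD ~ sampling SD of the mean count
  set.seed(11)
  n <- 5000
  y <- rbinom(n, 50, 0.1)
  ev2 <- data.frame(camera_id = rep(sprintf("c%04d", 1:n), y))
  eff2 <- data.frame(camera_id = sprintf("c%04d", 1:n), active_days = rep(1, n))
  b2 <- bootstrap_trap_rate(ev2, eff2, n_iterations = 4000, seed = 3)
  analytic <- sqrt(50 * 0.1 * 0.9 / n)
  expect_lt(abs(b2$boot_sd - analytic) / analytic, 0.05)
  # reproducibility: identical (seed, data) -> identical estimate
  b3 <- bootstrap_trap_rate(ev2, eff2, n_iterations = 4000, seed = 3)
  expect_identical(b2$draws, b3$draws)
  expect_warning(bootstrap_trap_rate(ev, eff, n_iterations = 50, seed = 1),
                 "100")
})

test_that("delta-method CV matches a Monte-Carlo propagation oracle", {
  zone <- detection_zone(0.0116, 0.698, radius_se = 0.0016, arc_se = 0.07)
  est <- rem_variance(rate = 0.03, rate_sd = 0.006, v = 0.28, v_se = 0.04,
                      zone = zone, seed = 4)
  set.seed(99)
  n <- 2e5
  rtnorm <- function(n, m, s) {
    x <- rnorm(n, m, s)
    while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), m, s)
    x
  }
  rr <- pmax(rnorm(n, 0.03, 0.006), 0)
  vv <- rtnorm(n, 0.28, 0.04)
  rd <- rtnorm(n, 0.0116, 0.0016)
  th <- rtnorm(n, 0.698, 0.07)
  dmc <- (rr / 24) * pi / (vv * rd * (2 + th))
  cv_mc <- sd(dmc) / mean(dmc)
  expect_lt(abs(est$cv - cv_mc) / cv_mc, 0.10)
})

test_that("rem_variance degenerates and orders correctly", {
  zone0 <- detection_zone(0.0116, 0.698)
  est0 <- rem_variance(rate = 0.03, rate_sd = 0, v = 0.28, v_se = 0,
                       zone = zone0)
  expect_equal(est0$cv, 0)
  expect_equal(est0$ci[1], est0$density_per_10km2)
  expect_equal(est0$ci[2], est0$density_per_10km2)
  expect_equal(est0$density_per_10km2, 10 * est0$density)
  # inflating only the speed SE strictly increases the CV
  est1 <- rem_variance(0.03, v = 0.28, v_se = 0.02, zone = zone0)
  est2 <- rem_variance(0.03, v = 0.28, v_se = 0.06, zone = zone0)
  expect_gt(est2$cv, est1$cv)
})

test_that("speed correction follows the v/(1-f) convention", {
  expect_equal(apply_speed_correction(0.233, 0), 0.233)
  expect_equal(apply_speed_correction(0.233, 0.6), 0.5825)
  # corrected density = uncorrected * (1 - f), since D is proportional to 1/v
  zone <- detection_zone(0.0116, 0.698)
  d0 <- rem_density(0.03, 0.233, zone)
  d1 <- rem_density(0.03, apply_speed_correction(0.233, 0.6), zone)
  expect_equal(d1, d0 * (1 - 0.6))
  expect_error(apply_speed_correction(0.3, 1), "fraction")
})

test_that("REM on simulated gas-model data recovers the true density", {
  w <- gas_world()
  ev <- detect_camera_events(w$paths, w$cams,
                             event_gap = w$params$step_interval * 60)
  eff <- data.frame(camera_id = w$cams$camera_id,
                    active_days = w$duration / 24)
  d_hat <- rem_density(trap_rate(ev, eff), 0.28, w$zone)
  cv_mc <- 1 / sqrt(nrow(ev))
  expect_lt(abs(d_hat - w$d_true) / w$d_true, 0.05 + 3 * cv_mc)
})
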