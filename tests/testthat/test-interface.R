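make_photo_csv <- function(path) {
  writeLines(c("camera_id,timestamp,species",
               "C01,2015-07-02T10:00:00,black_bear",
               "C01,2015-07-02T10:00:02,black_bear",
               "C01,2015-07-02T10:15:00,black_bear",
               "C02,2015-07-03T06:00:00,moose",
               "C02,2015-07-04T12:00:00,black_bear"), path)
  path
}

make_effort_csv <- function(path) {
  writeLines(c("camera_id,x_km,y_km,start,end,r_m,r_se_m,theta_rad,theta_se_rad",
               "C01,1.0,2.0,2015-07-01T00:00:00,2015-08-20T00:00:00,11.6,0.63,0.698,0.07",
               "C02,3.5,1.2,2015-07-01T00:00:00,2015-08-10T00:00:00,11.6,0.63,0.698,0.07"),
             path)
  path
}

test_that("photo and effort readers validate, filter and sort", {
  pf <- make_photo_csv(tempfile(fileext = ".csv"))
  rec <- read_photo_records(pf)
  expect_equal(nrow(rec), 5)
  expect_true(!is.unsorted(rec$timestamp[rec$camera_id == "C01"]))
  expect_message(recb <- read_photo_records(pf, species = "black_bear"),
                 "1 record")
  expect_equal(nrow(recb), 4)

  ef <- make_effort_csv(tempfile(fileext = ".csv"))
  eff <- read_effort_table(ef)
  expect_equal(eff$active_days, c(50, 40))
  zone <- pooled_zone(eff)
  expect_equal(zone$radius_r, 0.0116)
  expect_equal(zone$arc_theta, 0.698)

  # missing required column is named in the error
  bad <- tempfile(fileext = ".csv")
  writeLines(c("camera_id,species", "C01,bear"), bad)
  expect_error(read_photo_records(bad), "timestamp")
  # malformed timestamps are reported with their row
  ugly <- tempfile(fileext = ".csv")
  writeLines(c("camera_id,timestamp,species", "C01,not-a-time,bear"), ugly)
  expect_error(read_photo_records(ugly), "row")
})

test_that("synthetic data round-trip through the writers and readers", {
  # telemetry
  fixes <- data.frame(animal_id = rep("A1", 4), population = "simpop",
                      timestamp = as.POSIXct("2015-07-01 00:00:00", tz = "UTC") +
                        3600 * (0:3),
                      x = c(0, 0.1, 0.25, 0.3), y = c(0, 0.05, 0.05, 0.2))
  tf <- tempfile(fileext = ".csv")
  write_telemetry(fixes, tf)
  back <- read_telemetry(tf)
  expect_equal(back$x, fixes$x)
  expect_equal(back$timestamp, fixes$timestamp)
  expect_equal(average_speed(segment_speeds(back))$v_mean,
               average_speed(segment_speeds(fixes))$v_mean)

  # capture history + traps
  traps <- default_trap_grid()
  hist <- simulate_scr_captures(scr_sim_config(true_density = 0.5),
                                traps, extent = c(-2, 16, -2, 16), seed = 5)
  cf <- tempfile(fileext = ".csv"); trf <- tempfile(fileext = ".csv")
  write_capture_history(hist, cf)
  write_trap_array(traps, trf)
  traps2 <- read_trap_array(trf)
  hist2 <- read_capture_history(cf, n_occasions = hist$n_occasions,
                                trap_ids = as.character(traps2$trap_id))
  expect_equal(traps2$x, traps$x)
  expect_setequal(hist2$individuals, hist$individuals)
  expect_equal(nrow(hist2$captures), nrow(hist$captures))
  expect_equal(unname(hist2$sex[hist$individuals]),
               unname(hist$sex[hist$individuals]))
})

test_that("GeoJSON masks parse down to a vertex matrix", {
  gj <- tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(list(
    type = "Feature",
    geometry = list(type = "Polygon",
                    coordinates = list(list(c(0, 0), c(4, 0), c(4, 4), c(0, 4),
                                            c(0, 0)))),
    properties = list(name = "landmask")), auto_unbox = TRUE), gj)
  m <- read_mask_geojson(gj)
  expect_equal(ncol(m), 2)
  expect_gte(nrow(m), 4)
  inside <- point_in_polygon(c(2, 5), c(2, 2), m)
  expect_identical(inside, c(TRUE, FALSE))
})

test_that("the full comparison reproduces the printed REM table", {
  zone <- detection_zone(0.0116, 0.698, radius_se = 0.00063, arc_se = 0.07)
  config <- list(
    seed = 1,
    rem = list(events = ref_events(), efforts = ref_efforts(), zone = zone,
               boot_iterations = 2000),
    speeds = data.frame(population = c("popA", "popB", "popC",
                                       "popD"),
                        v = c(0.233, 0.258, 0.309, 0.309),
                        v_se = c(0.315, 0.306, 0.584, 0.449) /
                          sqrt(c(3063, 26094, 1567, 21867))))
  res <- run_full_comparison(config)
  expect_equal(round(res$rem_table$density_10km2, 2), c(5.38, 4.86, 4.06, 4.06))
  expect_true(all(res$rem_table$ci_lower_10km2 <= res$rem_table$density_10km2))
  expect_true(all(res$rem_table$ci_upper_10km2 >= res$rem_table$density_10km2))
  expect_null(res$scr)

  # determinism: identical config and seeds -> identical results
  res2 <- run_full_comparison(config)
  r1 <- res; r1$provenance$timestamp <- NULL
  r2 <- res2; r2$provenance$timestamp <- NULL
  expect_identical(r1, r2)

  # unknown keys are rejected
  bad <- config; bad$typo <- 1
  expect_error(run_full_comparison(bad), "unknown config key")
})

test_that("a fully synthetic end-to-end run covers the simulation truth", {
  # REM arm
  w <- gas_world(n_cameras = 40, duration = 300, d_true = 2, side = 8,
                 seed = 55)
  ev <- detect_camera_events(w$paths, w$cams,
                             event_gap = w$params$step_interval * 60)
  eff <- data.frame(camera_id = w$cams$camera_id,
                    active_days = w$duration / 24)
  rate <- bootstrap_trap_rate(ev, eff, n_iterations = 2000, seed = 6)
  est <- rem_variance(rate, v = 0.28, v_se = 0.28 * 0.03,
                      zone = w$zone, seed = 7)
  expect_gt(10 * w$d_true, est$ci[1])
  expect_lt(10 * w$d_true, est$ci[2])

  # SCR arm on a reduced world
  ws <- small_scr_world(seed = 19, d_true = 0.8)
  fit <- run_mcmc(ws$history, ws$traps, ws$space, scr_model_spec(M = 120),
                  mcmc_config(n_chains = 2, n_iterations = 4000,
                              n_burnin = 1000, seed = 8))
  d <- density_posterior(fit)
  d_true <- ws$truth$N / ws$space$total_area
  expect_gt(d_true, d[["lower"]])
  expect_lt(d_true, d[["upper"]])
})

test_that("the CLI rem and sensitivity subcommands run end to end", {
  pf <- make_photo_csv(tempfile(fileext = ".csv"))
  ef <- make_effort_csv(tempfile(fileext = ".csv"))
  out <- tempfile(fileext = ".json")
  suppressMessages(
    res <- remscr_cli(c("rem", "--photos", pf, "--effort", ef,
                        "--species", "black_bear",
                        "--speed", "0.233", "--speed-se", "0.006",
                        "--boot-iters", "500", "--seed", "3",
                        "--out", out)))
  expect_true(file.exists(out))
  parsed <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(parsed$n_events, 3)
  expect_equal(parsed$trap_rate, 3 / 90, tolerance = 1e-9)
  expect_equal(parsed$density_per_10km2, res$density_per_10km2,
               tolerance = 1e-6)

  outcsv <- tempfile(fileext = ".csv")
  remscr_cli(c("sensitivity", "--rate", "0.02996", "--v-min", "0.1",
               "--v-max", "1", "--n", "10", "--out", outcsv))
  curve <- read.csv(outcsv)
  expect_equal(nrow(curve), 10)
  expect_true(all(diff(curve$density_per_10km2) < 0))

  expect_error(remscr_cli(c("nope")), "unknown subcommand")
  expect_error(remscr_cli(c("rem", "--photos")), "needs a value")
})
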