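# Shared fixture builders. Everything is generated in code; seeds fixed
# so expectations are deterministic.

ref_zone <- function() detection_zone(0.0116, 0.698,
                                      radius_se = 0.00063, arc_se = 0.07)

# the reference survey's printed inputs: 67 events over 2,236 camera-days
# spread across 99 camera locations (36 of them with events)
ref_events <- function() {
  cams <- sprintf("C%02d", 1:99)
  counts <- integer(99)
  counts[1:36] <- rep_len(c(3, 2, 2, 1, 1, 1), 36)
  counts[1:36] <- counts[1:36] + c(rep(1, 67 - sum(counts)), rep(0, 36 - (67 - sum(counts))))
  stopifnot(sum(counts) == 67)
  data.frame(camera_id = rep(cams, counts))
}

ref_efforts <- function() {
  data.frame(camera_id = sprintf("C%02d", 1:99),
             active_days = rep(2236 / 99, 99))
}

# small ideal-gas world reused by unit tests (scaled down from the
# 100-camera acceptance world). Step = r/10 keeps the finite-step entry
# undercount ~5%; kappa = 10 makes movement ballistic at the zone scale
# (the gas model's straight-pass regime) while still isotropic overall.
gas_world <- function(n_cameras = 30, duration = 200, d_true = 5,
                      side = 5, seed = 33, kappa = 10) {
  ar <- arena(side, side, "wrap")
  mp <- movement_params(mean_speed = 0.28, speed_sd = 0,
                        turn_concentration = kappa,
                        step_interval = (0.0116 / 10) / 0.28)
  paths <- simulate_movement(ar, n_animals = round(d_true * side^2), mp,
                             duration = duration, seed = seed)
  zone <- detection_zone(0.0116, 0.698)
  cams <- camera_array(n_cameras, ar, zone, seed = seed + 1)
  list(arena = ar, params = mp, paths = paths, zone = zone, cams = cams,
       duration = duration, d_true = d_true)
}

# tiny SCR world for fast sampler tests: 9 traps, coarse grid
small_scr_world <- function(seed = 7, d_true = 0.5, g0 = 0.6, sigma = 0.6,
                            n_occasions = 5) {
  traps <- data.frame(trap_id = sprintf("T%d", 1:9),
                      x = rep(c(0, 1.5, 3), 3), y = rep(c(0, 1.5, 3), each = 3))
  space <- build_state_space(traps, buffer = 3, resolution = 0.75)
  cfg <- scr_sim_config(true_density = d_true, g0 = g0, sigma = sigma,
                        theta_det = 0.75, n_occasions = n_occasions)
  hist <- simulate_scr_captures(cfg, traps, extent = space, seed = seed)
  list(traps = traps, space = space, cfg = cfg, history = hist,
       truth = attr(hist, "truth"))
}
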