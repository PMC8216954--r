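# remscr

Population-density estimation for unmarked animals from camera traps via
the **random encounter model (REM)**, validated against a **Bayesian
spatial capture–recapture (SCR)** reference estimator — the workflow used
to assess whether a cheap camera grid can replace DNA-based hair-snag
surveys for black bears, and how sensitive the camera estimate is to the
movement-speed parameter it must import from telemetry.

The package is aimed at quantitative ecologists who have (a) photo
records and camera deployment logs, (b) GPS telemetry from the same or a
related population, and optionally (c) individual capture histories from
hair snags or similar marked-detector arrays.

## The models

**REM.** Treating animal–camera contacts as ideal-gas collisions, density
follows from the trap rate `y/t` (independent events per camera-hour),
the average speed `v` (km/h), and the sector-shaped detection zone
(radius `r` km, arc `θ` rad):

    D = (y/t) · π / (v · r · (2 + θ))

Uncertainty combines a camera-location bootstrap of `y/t` with the delta
method, `CV²(D) = CV²(y/t) + CV²(v) + CV²(r) + Var(θ)/(2+θ)²`.

**SCR.** A data-augmentation formulation: `z_i ~ Bern(ψ)` inclusion
indicators over `M = 400` pseudo-individuals, activity centers on a
gridded state space (trap array + 6-km buffer), and a cloglog
distance-decay detection function

    p(d) = 1 − exp(−exp(α₀ + β·b + sex) · exp(−(d²/σ²)^θ)),

fit by a compiled Metropolis-within-Gibbs sampler with Gelman–Rubin
diagnostics and the classical Otis closure test.

A movement/detection simulator (correlated random walks, sector zones,
distance-decaying hair-snag captures, GPS fix schedules) makes the whole
pipeline testable end to end without field data.

## Worked example

Using the published survey inputs — 67 independent bear events over
2,236 camera-days, zone r = 11.6 m, θ = 0.698 rad — and the range of
telemetry speeds (0.233–0.309 km/h) from four source populations:

```r
library(remscr)
zone <- detection_zone(0.0116, 0.698, radius_se = 0.00063, arc_se = 0.07)
rate <- 67 / 2236
round(10 * rem_density(rate, v = 0.233, zone), 2)
#> [1] 5.38
round(10 * rem_density(rate, v = 0.309, zone), 2)
#> [1] 4.06
```

So the camera estimate spans 4.06–5.38 individuals/10 km² depending on
which population's speed is imported — bracketing, from above, the
hair-snag SCR reference of ~2.9/10 km² that this design reproduces in
simulation.

Sensitivity to a small absolute speed error is asymmetric (density ∝
1/v):

```r
fast <- perturbation_effect(rate, zone, v0 = 1.0,  delta_v = 0.015)
slow <- perturbation_effect(rate, zone, v0 = 0.10, delta_v = 0.015)
round(c(fast$delta_d, slow$delta_d), 2)
#> [1] 0.02 1.63
sensitivity_ratio(slow, fast)
#> [1] 88.26087
```

A +0.015 km/h error moves the estimate by 0.02 individuals/10 km² for a
fast mover (1 km/h) but by ~2 individuals/10 km² for a slow one
(0.10 km/h) — nearly two orders of magnitude.

Fully synthetic SCR round trip:

```r
traps <- default_trap_grid()                      # 33 stations, ~7.5 km² cells
space <- build_state_space(traps, buffer = 6, resolution = 0.5)
hist  <- simulate_scr_captures(scr_sim_config(), traps, space, seed = 11)
fit   <- run_mcmc(hist, traps, space, scr_model_spec(M = 400),
                  mcmc_config(seed = 5))
print(fit)
#> SCR fit: 34 observed individuals, M = 400, 3 chains x 15000 draws (post burn-in)
#>   density: 0.252 /km^2 (2.52 /10 km^2), 95% CrI [1.52, 4.16] /10 km^2
#>   sigma: Rhat = 1.003
#>   g0: Rhat = 1.003
#>   theta: Rhat = 1.004
```

(the simulation truth for that seed is 185 animals on 676 km², i.e.
2.74/10 km², inside the credible interval).

There is also a small CLI:

```sh
Rscript -e 'remscr::remscr_cli()' rem --photos photos.csv --effort effort.csv \
    --speed 0.233 --speed-se 0.006 --seed 1
Rscript -e 'remscr::remscr_cli()' sensitivity --rate 0.02996 --v-min 0.05 --v-max 1.2 --out curve.csv
```

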