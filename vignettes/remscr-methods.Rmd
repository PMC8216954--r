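---
title: "Density estimation with remscr: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density estimation with remscr: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remscr)
```

## The problem

Estimating the density of a large, unmarked, mobile mammal from camera
traps is attractive because cameras are cheap to redeploy, but the
standard estimator for such data — the random encounter model (REM) —
imports a movement-speed parameter that usually comes from telemetry on
*other* populations. `remscr` implements the full comparison workflow
around that question: the REM with honest uncertainty propagation, a
Bayesian spatially explicit capture–recapture (SCR) estimator that serves
as the marked-population reference, telemetry speed estimation with the
filters that matter, a sensitivity analysis of the REM to its speed
input, and a simulator that generates movement paths, camera events,
hair-snag capture histories and GPS fix schedules with the statistical
structure all of the above assume.

## The random encounter model

The REM treats animal–camera contacts like collisions in a
two-dimensional ideal gas. With trap rate $y/t$ (independent events per
unit effort), average speed $v$ (km/h) and a sector-shaped detection
zone of radius $r$ (km) and arc $\theta$ (radians),

$$D = \frac{y}{t}\cdot\frac{\pi}{v\,r\,(2+\theta)}.$$

Internally effort is typed in camera-days and converted to hours inside
`rem_density()`, so the unit error the formula invites (camera-days vs
camera-hours) cannot happen through the public interface. Densities are
stored per km² and displayed per 10 km², the conventional reporting
scale for bears.

**Events.** Cameras fire bursts of consecutive pictures. `build_events()`
merges, per camera, any photos separated by at most `event_gap` minutes
(default 10) into a single event; a return *strictly* later than the gap
opens a new event. The strictness matters at the boundary: two photos
exactly 10 minutes apart are one event.

**Trap-rate uncertainty.** `bootstrap_trap_rate()` resamples whole
cameras (their event count and effort together) with replacement —
cameras, not photos, are the independent sampling units. The point
estimate is the pooled ratio $\sum y_c / \sum t_c$ by default; the
unweighted mean of per-camera rates is available (`method = "mean"`)
because the two differ on real data and published summaries are
ambiguous about which was used. The default of 10,000 iterations is set
by quantile stability; the historical figure of 350,000 is available via
the argument.

**Delta method.** `rem_variance()` combines the component uncertainties
as
$$\mathrm{CV}^2(D) = \mathrm{CV}^2(y/t) + \mathrm{CV}^2(v)
  + \mathrm{CV}^2(r) + \frac{\mathrm{Var}(\theta)}{(2+\theta)^2},$$
the first-order propagation for a product/quotient form with the
$(2+\theta)$ term linearised. The 95% interval is *not* the delta-method
normal interval: it is the 2.5/97.5% quantiles of a resampling
distribution combining the trap-rate bootstrap draws with independent
zero-truncated normal draws of $v$, $r$ and $\theta$. A trap-rate-only
interval is available (`include_param_uncertainty = FALSE`) because
published confidence intervals are ambiguous about whether parameter
uncertainty was included; the default includes it, consistent with the
delta-method CV.

**Speed correction.** Coarse GPS schedules hide tortuosity, so telemetry
speeds underestimate travel speed; reports around 60% underestimation at
2-hour fix intervals are common for large mammals.
`apply_speed_correction(v, f)` uses the convention that the observed
speed is $(1-f)$ of the truth, i.e. corrected $v' = v/(1-f)$, so the
corrected density is $(1-f)$ times the uncorrected one. This convention
is a documented choice: the literature states the underestimation
percentage without fixing the algebra, and no single multiplier
reproduces every published corrected range, so the fraction is exposed
as a parameter rather than hard-coded.

## Movement speed from telemetry

`segment_speeds()` computes one speed per consecutive fix pair (distance
over elapsed time, never spanning animals). `filter_segments()` applies
the two filters that matter in practice: a July–September month-day
window (inclusive on both ends, evaluated at the segment start) and a
maximum segment duration of 3 hours — the per-segment version of a
"minimum 8 locations/day" rule, which is robust to irregular schedules.
Zero-length segments are retained for mean speed but dropped (and
counted) by the log-scale ANOVA, since log(0) is undefined.

`variance_decomposition()` fits a one-factor ANOVA of log speed on
population identity and reports the percentage of the total sum of
squares attributed to the factor (interpopulation variation) versus the
residual (intrapopulation). For a single factor the type III and
sequential decompositions coincide, so `lm()`/`anova()` are used
directly. Whether to average speeds per segment (pooled) or per animal
first is genuinely open; pooled is the default because published sample
sizes are stated in locations, not animals.

`fix_rate_bias_curve()` quantifies the fix-interval bias by thinning
simulated paths with `sample_gps_fixes()` and recomputing the mean
speed; by the triangle inequality the estimate is non-increasing in the
interval, and for an uncorrelated walk the loss at 2-hour sampling
relative to 15-minute sampling exceeds 40%.

## Bayesian spatial capture–recapture

The reference estimator is an SCR model fit by data augmentation. The
population is padded to $M = 400$ pseudo-individuals with inclusion
indicators $z_i \sim \mathrm{Bernoulli}(\psi)$; abundance is
$N = \sum z_i$ and density is $N$ divided by the state-space area.
Activity centers live on a discrete grid (`build_state_space()`): the
trap bounding box plus a 6-km buffer — three radii of a 10.77-km²
circular home range, rounded up — at 0.5-km resolution, optionally
clipped to a land mask.

**Detection.** The probability that individual $i$ is caught at trap $j$
on an occasion is a complementary log-log hazard with a stretched
distance kernel:
$$p_{ij} = 1 - \exp\!\big(-e^{\alpha_0 + \beta b + s}\,
  e^{-(d_{ij}^2/\sigma^2)^{\theta}}\big),$$
where $b$ is the trap-happy/shy indicator switching after the first
capture anywhere, $s$ a sex offset, $\sigma$ the movement scale and
$\theta \in [0.5, 1]$ interpolates an exponential kernel ($\theta=0.5$)
to a Gaussian one ($\theta=1$). The software that popularised this
parameterisation never published the equation; this form is the
conventional reading and is stated here explicitly so results are
reproducible. `g0 = 1 - exp(-exp(alpha0))` is the baseline detection
probability. The observation model is Bernoulli per individual × trap ×
occasion: hair snags can catch many bears per week, so there is no
multi-catch exclusivity. Eight candidate models arise from putting sex
and/or behaviour on $g_0$ and sex on $\sigma$; all are fittable
(`scr_model_spec()`). Bayes-factor model ranking is *not* implemented —
the method behind published rankings is undocumented.

**Priors and starting values.** Flat (improper) priors on $\alpha_0$,
$\beta$ and the sex offsets; flat on $(0,\infty)$ for $\sigma$; uniform
(0.5, 1) for $\theta$; uniform (0, 1) for $\psi$ and $\psi_{sex}$.
Starting values follow the reference analysis: $\sigma = 1$,
$\theta = 0.75$, $\alpha_0 = -4.01$, $\beta = 0$, $\psi = 0.5$,
$\psi_{sex} = 0.31$. The published "$\ln(\alpha_0) = -4.01$" notation is
internally odd; it is read here as the starting value of the log-hazard
intercept, and with burn-in adaptation the chains leave it within a few
hundred iterations either way.

**Sampler.** Metropolis-within-Gibbs, compiled (Rcpp). Scalar parameters
use random-walk proposals adapted during burn-in toward 20–40%
acceptance and frozen afterwards (preserving detailed balance for the
retained draws). Activity centers move by a mixture of local
(1.5-km-neighbourhood, Hastings-corrected for edge degree) and global
uniform proposals; centers of excluded individuals ($z_i=0$) are prior
draws. $\psi$ and $\psi_{sex}$ are conjugate Beta updates. Because
$\log(1-p) = -\lambda$ under the cloglog form, an all-zero (augmented)
history costs a single kernel sum $S(g)=\sum_j k(d_{gj})$ per grid
point, which is cached and invalidated only when $\sigma$ or $\theta$
moves; kernel terms below $10^{-13}$ are dropped via per-point sorted
trap distances. These are exact-likelihood optimisations, not
approximations, apart from the $10^{-13}$ tail truncation.

Scaled-down defaults (3 chains × 20,000 iterations, 5,000 burn-in) are
used for testing; the full-scale setting (3 × 400,000, 50,000 burn-in)
is a config away. Convergence is monitored with the Gelman–Rubin
statistic (`gelman_rubin()`, classical $\hat R$ with the $(n-1)/n$
finite-sample factor; < 1.1 is the working threshold); non-convergence
is reported, never raised as an error.

**Closure.** `otis_closure_test()` implements the classical closure test
from capture–recapture theory: for each individual caught on $\ge 2$
occasions, the span between first and last capture occasion is compared
with its exact null moments under exchangeable capture occasions
(computed by enumeration of $n$-subsets of $K$), and the standardized
sum is referred to the standard normal lower tail, $p = \Phi(z)$ — small
$p$ means short spans, i.e. animals present only part of the study. A
permutation fallback (`n_perm`) checks the normal approximation's
direction.

## The synthetic world

The simulator is first-class, tested code; it generates what the
estimators assume, with defaults chosen once from the study system:

* **Movement** (`simulate_movement()`): correlated random walk; step
  speeds gamma with mean ≈ 0.23–0.31 km/h (the published range for the
  four bear populations), headings persisting with von Mises turning
  angles. `turn_concentration = 0` is uncorrelated movement.
  Reflective boundaries by default (a closed park); a torus (`wrap`) for
  edge-free gas-model checks.
* **Cameras** (`detect_camera_events()`): sector zones with r = 11.6 m,
  θ = 0.698 rad; detection is evaluated at discrete fix positions, so
  the contract requires step length ≪ r (default step = r/3).
* **Hair snags** (`simulate_scr_captures()`): activity centers uniform,
  expected count density × area; captures from the same cloglog model
  the estimator fits, with the behavioural offset switching after first
  capture. Defaults are the reference point estimates (D = 0.287/km²,
  g0 = 0.59, σ = 0.74 km, θ = 0.75, 5 occasions, 31% male).
* **GPS** (`sample_gps_fixes()`): nearest-native-fix thinning with
  optional isotropic position noise.

**What a green test does not establish.** The simulator has no habitat
heterogeneity, home-range attraction, lure response, or density
gradients; activity centers do not move; camera detection is perfect
within the sector and zero outside. Recovery of truth here shows the
estimators are internally consistent with their own assumptions — it
says nothing about robustness to the many ways field data violate them.

### Numerical fine print of the gas-model validation

Two discretisation effects surfaced while validating the REM against the
simulator, and both are worth recording:

1. *Finite steps undercount zone entries.* With step length $L$, the
   per-step probability of an outside→inside transition is the
   direction-averaged area of $(Z - s)\setminus Z$, which is below the
   continuum flux $L\,r(2+\theta)/\pi$ by roughly $0.6\,L/r$ (measured:
   −20% at $L = r/3$, −5% at $L = r/10$). Validation worlds therefore
   use step = r/10; the general default stays at r/3, which is fine for
   generating realistic event data but not for closed-form comparisons
   at the percent level.
2. *Event gap versus movement regime.* The closed form counts zone
   entries. For uncorrelated-heading movement the path is diffusive at
   the 11.6-m zone scale and re-enters immediately after leaving, so the
   10-minute field rule would merge distinct crossings (~3× undercount);
   gas-model checks therefore merge only consecutive in-zone fixes
   (event gap = one step). With heading persistence ≈ 10 the walk is
   ballistic at the zone scale — the gas model's own regime — and camera
   counts are near-Poisson; with persistence 0 the counts are heavily
   overdispersed (single excursions produce clusters of re-entries),
   which the validation tolerances acknowledge by using fixed seeds and
   flux means, which remain exact for any stationary isotropic motion.

## Worked example

```{r}
zone <- detection_zone(0.0116, 0.698, radius_se = 0.00063, arc_se = 0.07)
rate <- 67 / 2236                      # events per camera-day
round(10 * rem_density(rate, v = 0.233, zone), 2)  # individuals / 10 km^2
round(10 * rem_density(rate, v = 0.309, zone), 2)

# asymmetric sensitivity to an absolute speed error of 0.015 km/h
fast <- perturbation_effect(rate, zone, v0 = 1.0, delta_v = 0.015)
slow <- perturbation_effect(rate, zone, v0 = 0.10, delta_v = 0.015)
c(fast = fast$delta_d, slow = slow$delta_d,
  ratio = sensitivity_ratio(slow, fast))
```

## Known limitations

* The SCR state space is a rectangle-plus-mask grid; irregular trap
  layouts with concave hulls waste grid points (cost, not bias).
* The sampler's tail truncation ($k < 10^{-13}$) and the discrete
  activity-center grid (0.5 km) are the only likelihood approximations;
  both are far below posterior Monte-Carlo error at realistic scales.
* Bayes-factor model ranking and genotyping-error models are out of
  scope; `scr_model_spec()` fits the candidate set but does not rank it.
* Speed-correction uncertainty is not propagated: `apply_speed_correction`
  shifts the point estimate only, since no variance for the correction
  factor is available in the literature it comes from.
* All coordinates are planar km; projecting geographic data is the
  caller's job.
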