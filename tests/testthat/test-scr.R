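test_that("state-space construction follows the grid arithmetic", {
  trap <- data.frame(trap_id = "T1", x = 10, y = 10)
  sp <- build_state_space(trap, buffer = 6, resolution = 0.5)
  expect_equal(nrow(sp$grid), 625)            # 25 x 25
  expect_equal(range(sp$grid[, 1]), c(4, 16)) # [x-6, x+6]
  expect_equal(range(sp$grid[, 2]), c(4, 16))
  expect_equal(sp$total_area, 156.25)
  # halving the resolution about quadruples the point count
  sp2 <- build_state_space(trap, buffer = 6, resolution = 0.25)
  expect_equal(nrow(sp2$grid), 49^2)
  # the default 6-km buffer is 3 home-range radii rounded up
  expect_gte(6, 3 * sqrt(10.77 / pi))
  expect_lt(3 * sqrt(10.77 / pi), 6)
  # mask clipping drops outside points
  mask <- cbind(c(4, 16, 16, 4), c(4, 4, 10, 10))
  spm <- build_state_space(trap, buffer = 6, resolution = 0.5, mask = mask)
  expect_true(all(spm$grid[, 2] < 10))
  expect_lt(spm$total_area, sp$total_area)
})

test_that("detection function interpolates exponential to Gaussian kernels", {
  a0 <- 0.2; sig <- 0.8
  for (d in c(0, sig, 2 * sig)) {
    # theta = 1: Gaussian (half-normal) kernel
    expect_equal(detection_probability(d, list(alpha0 = a0, sigma = sig,
                                               theta_det = 1)),
                 1 - exp(-exp(a0) * exp(-(d / sig)^2)))
    # theta = 0.5: exponential kernel
    expect_equal(detection_probability(d, list(alpha0 = a0, sigma = sig,
                                               theta_det = 0.5)),
                 1 - exp(-exp(a0) * exp(-d / sig)))
  }
  # strictly decreasing in distance (until underflow), vanishing far out
  p <- detection_probability(seq(0, 4, 0.25),
                             list(alpha0 = a0, sigma = sig, theta_det = 0.75))
  expect_true(all(diff(p) < 0))
  expect_lt(detection_probability(10, list(alpha0 = a0, sigma = sig,
                                           theta_det = 0.75)), 1e-6)
  # cloglog inversion: g0 = 0.59 corresponds to alpha0 ~ -0.116
  expect_equal(g0_to_alpha0(0.59), log(-log(1 - 0.59)))
  expect_equal(round(g0_to_alpha0(0.59), 3), -0.115)
  expect_equal(alpha0_to_g0(g0_to_alpha0(0.59)), 0.59)
  expect_equal(detection_probability(0, list(alpha0 = g0_to_alpha0(0.59),
                                             sigma = 1, theta_det = 0.75)),
               0.59)
  expect_error(detection_probability(1, list(alpha0 = 0, sigma = -1,
                                             theta_det = 1)), "sigma")
})

test_that("Gelman-Rubin matches a hand calculation and its limits", {
  # exact copies -> 1 (up to the classical (n-1)/n finite-sample factor)
  expect_equal(gelman_rubin(list(rep(1:1000, 2), rep(1:1000, 2))), 1,
               tolerance = 1e-3)
  # hand-computed oracle on two 4-draw chains
  c1 <- c(1, 2, 3, 4); c2 <- c(101, 102, 103, 104)
  W <- (var(c1) + var(c2)) / 2
  B <- 4 * var(c(mean(c1), mean(c2)))
  oracle <- sqrt((3 / 4 * W + B / 4) / W)
  expect_equal(gelman_rubin(list(c1, c2)), oracle)
  expect_error(gelman_rubin(list(c1)), "2 chains")
  # Rhat shrinks toward 1 as offset chains are extended with common draws
  set.seed(20)
  base1 <- rnorm(50, 0); base2 <- rnorm(50, 3)
  extra <- rnorm(2000); extra2 <- rnorm(2000)
  r_short <- gelman_rubin(list(base1, base2))
  r_long <- gelman_rubin(list(c(base1, extra), c(base2, extra2)))
  expect_lt(r_long, r_short)
  expect_lt(r_long, 1.2)
})

test_that("Otis closure test reproduces the printed convention", {
  # z = 0.33 maps to p = 0.63 under the lower-tail normal convention
  expect_equal(round(pnorm(0.33), 2), 0.63)

  # spans spread across all occasions -> large p; compressed -> small p
  K <- 5
  spread <- capture_history(data.frame(
    individual_id = rep(sprintf("i%d", 1:10), each = 2),
    trap_id = "T1", occasion = rep(c(1L, 5L), 10)), n_occasions = K)
  tight <- capture_history(data.frame(
    individual_id = rep(sprintf("i%d", 1:10), each = 2),
    trap_id = "T1", occasion = rep(c(2L, 3L), 10)), n_occasions = K)
  set.seed(31)
  r_spread <- otis_closure_test(spread, n_perm = 2000)
  r_tight <- otis_closure_test(tight, n_perm = 2000)
  expect_gt(r_spread$p, 0.5)
  expect_lt(r_tight$p, 0.05)
  # permutation fallback agrees in direction with the normal approximation
  expect_gt(r_spread$p_perm, 0.5)
  expect_lt(r_tight$p_perm, 0.05)
  # exact span moments: for n = 2 of K = 5, E[span] = (K+1)(n-1)/(n+1) = 2
  one <- capture_history(data.frame(individual_id = c("a", "a"),
                                    trap_id = "T1", occasion = c(1L, 3L)),
                         n_occasions = 5)
  expect_equal(otis_closure_test(one)$z,
               (2 - 2) / sqrt(1))  # span 2, mu 2, var 1 (enumerated below)
  # enumeration check of the variance: spans of 2-subsets of {1..5}
  spans <- apply(combn(5, 2), 2, diff)
  expect_equal(mean(spans), 2)
  expect_equal(mean(spans^2) - 4, 1)
  expect_error(otis_closure_test(capture_history(
    data.frame(individual_id = "a", trap_id = "T1", occasion = 1L),
    n_occasions = 5)), "2 occasions")
})

test_that("marginal likelihood prefers the truth over perturbed parameters", {
  w <- small_scr_world(seed = 42)
  pars_true <- list(alpha0 = g0_to_alpha0(w$cfg$g0), sigma = w$cfg$sigma,
                    theta_det = w$cfg$theta_det)
  ll_true <- scr_marginal_loglik(w$history, w$traps, w$space, pars_true)
  pars_wide <- pars_true; pars_wide$sigma <- 2 * w$cfg$sigma
  ll_wide <- scr_marginal_loglik(w$history, w$traps, w$space, pars_wide)
  expect_gt(ll_true, ll_wide)
  expect_gt(nrow(w$space$grid), 100)  # a genuine grid average, not a point
})

test_that("the sampler recovers the prior for psi with no data", {
  hist0 <- capture_history(data.frame(individual_id = character(0),
                                      trap_id = character(0),
                                      occasion = integer(0)),
                           n_occasions = 0, trap_ids = c("T1", "T2"))
  traps <- data.frame(trap_id = c("T1", "T2"), x = c(0, 1), y = c(0, 1))
  space <- build_state_space(traps, buffer = 2, resolution = 0.5)
  fit <- run_mcmc(hist0, traps, space, scr_model_spec(M = 60),
                  mcmc_config(n_chains = 2, n_iterations = 4000,
                              n_burnin = 500, seed = 2))
  psi <- unlist(lapply(fit$chains, function(m) m[, "psi"]))
  # uniform(0,1) prior recovery: mean 1/2, variance 1/12
  expect_lt(abs(mean(psi) - 0.5), 0.03)
  expect_lt(abs(var(psi) - 1 / 12), 0.01)
  n <- unlist(lapply(fit$chains, function(m) m[, "N"]))
  expect_lt(abs(mean(n) - 30), 2)
})

test_that("MCMC draws are reproducible and respect hard constraints", {
  w <- small_scr_world(seed = 7)
  cfg <- mcmc_config(n_chains = 2, n_iterations = 1500, n_burnin = 500,
                     seed = 9)
  spec <- scr_model_spec(M = 80)
  fit1 <- run_mcmc(w$history, w$traps, w$space, spec, cfg)
  fit2 <- run_mcmc(w$history, w$traps, w$space, spec, cfg)
  expect_identical(fit1$chains, fit2$chains)
  draws <- do.call(rbind, fit1$chains)
  expect_true(all(draws[, "N"] <= 80))
  expect_true(all(draws[, "N"] >= length(w$history$individuals)))
  expect_true(all(draws[, "sigma"] > 0))
  expect_true(all(draws[, "theta"] >= 0.5 & draws[, "theta"] <= 1))
  expect_true(all(draws[, "psi"] > 0 & draws[, "psi"] < 1))
  expect_true(all(draws[, "g0"] > 0 & draws[, "g0"] < 1))
  # density draws are N over the state-space area
  expect_equal(draws[, "D"], draws[, "N"] / w$space$total_area)
})

test_that("covariate models fit and expose their extra parameters", {
  w <- small_scr_world(seed = 3, d_true = 0.8)
  cfg <- mcmc_config(n_chains = 2, n_iterations = 1200, n_burnin = 400,
                     seed = 4)
  fit <- run_mcmc(w$history, w$traps, w$space,
                  scr_model_spec(g0_covariates = c("sex", "behavior"),
                                 sigma_covariates = "sex", M = 80), cfg)
  draws <- do.call(rbind, fit$chains)
  expect_gt(var(draws[, "beta"]), 0)
  expect_gt(var(draws[, "asex"]), 0)
  expect_gt(var(draws[, "ssex"]), 0)
  expect_true(all(is.finite(draws)))
})

test_that("posterior density summarises pooled draws", {
  w <- small_scr_world(seed = 7)
  fit <- run_mcmc(w$history, w$traps, w$space, scr_model_spec(M = 80),
                  mcmc_config(n_chains = 2, n_iterations = 1500,
                              n_burnin = 500, seed = 9))
  d <- density_posterior(fit)
  pooled <- unlist(lapply(fit$chains, function(m) m[, "D"]))
  expect_equal(d[["mean"]], mean(pooled))
  expect_equal(d[["lower"]], quantile(pooled, 0.025, names = FALSE))
  expect_equal(d[["upper"]], quantile(pooled, 0.975, names = FALSE))
  expect_lt(d[["lower"]], d[["mean"]])
})
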