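# Bayesian spatial capture-recapture by data augmentation: state space,
# cloglog distance-decay detection, Metropolis-within-Gibbs sampler
# (compiled core), convergence diagnostics, posterior density summaries,
# and the Otis et al. (1978) demographic closure test.

#' Capture history container
#'
#' @param captures Data frame with `individual_id`, `trap_id`, `occasion`
#'   (1-based integer); repeated rows collapse to a single binary
#'   detection.
#' @param sex Per-individual labels in `{"M", "F", "unknown"}`, named by
#'   individual or in order of first appearance; `NULL` means all unknown.
#' @param n_occasions Total occasions (default: max observed).
#' @param trap_ids All trap identifiers (default: those observed).
#' @return Object of class `capture_history` with elements `captures`,
#'   `individuals`, `sex`, `n_occasions`, `trap_ids`.
#' @export
capture_history <- function(captures, sex = NULL, n_occasions = NULL,
                            trap_ids = NULL) {
  stopifnot(all(c("individual_id", "trap_id", "occasion") %in% names(captures)))
  captures$individual_id <- as.character(captures$individual_id)
  captures$trap_id <- as.character(captures$trap_id)
  captures$occasion <- as.integer(captures$occasion)
  captures <- unique(captures[c("individual_id", "trap_id", "occasion")])
  individuals <- unique(captures$individual_id)
  if (is.null(n_occasions)) n_occasions <- max(captures$occasion, 0L)
  if (nrow(captures) && (any(captures$occasion < 1) ||
                         any(captures$occasion > n_occasions)))
    stop("occasions must lie in 1..n_occasions", call. = FALSE)
  if (is.null(trap_ids)) trap_ids <- sort(unique(captures$trap_id))
  if (nrow(captures) && !all(captures$trap_id %in% trap_ids))
    stop("captures reference unknown traps", call. = FALSE)
  if (is.null(sex)) sex <- rep("unknown", length(individuals))
  if (!is.null(names(sex))) sex <- sex[individuals]
  sex <- as.character(sex)
  sex[is.na(sex) | !sex %in% c("M", "F")] <- "unknown"
  if (length(sex) != length(individuals))
    stop("sex must have one entry per individual", call. = FALSE)
  structure(list(captures = captures, individuals = individuals,
                 sex = setNames(sex, individuals),
                 n_occasions = as.integer(n_occasions),
                 trap_ids = trap_ids),
            class = "capture_history")
}

#' @export
print.capture_history <- function(x, ...) {
  cat(sprintf("capture history: %d individuals, %d detections, %d traps, %d occasions\n",
              length(x$individuals), nrow(x$captures), length(x$trap_ids),
              x$n_occasions))
  invisible(x)
}

#' Build a discrete state space around a trap array
#'
#' Regular grid of candidate activity-center locations covering the trap
#' bounding box plus a buffer. The default 6-km buffer is about three
#' times the radius of a 10.77-km^2 circular home range
#' (sqrt(10.77/pi) = 1.85 km, 3x = 5.55, rounded up to 6).
#'
#' @param traps Data frame with `trap_id`, `x`, `y` (km).
#' @param buffer Buffer width, km.
#' @param resolution Grid spacing, km.
#' @param mask Optional polygon (two-column matrix/data frame of x, y
#'   vertices, or the result of [read_mask_geojson()]); grid points
#'   outside it are dropped (e.g. to clip the state space to land).
#' @return Object of class `rem_state_space`: `grid` (G x 2 matrix),
#'   `cell_area` (km^2), `total_area`, `buffer`, `resolution`.
#' @export
build_state_space <- function(traps, buffer = 6, resolution = 0.5, mask = NULL) {
  stopifnot(all(c("x", "y") %in% names(traps)))
  if (buffer <= 0 || resolution <= 0)
    stop("buffer and resolution must be > 0", call. = FALSE)
  if (resolution > buffer)
    warning("resolution coarser than the buffer; the state space will be crude")
  xs <- seq(min(traps$x) - buffer, max(traps$x) + buffer, by = resolution)
  ys <- seq(min(traps$y) - buffer, max(traps$y) + buffer, by = resolution)
  grid <- cbind(x = rep(xs, times = length(ys)),
                y = rep(ys, each = length(xs)))
  if (!is.null(mask)) {
    poly <- as.matrix(as.data.frame(mask)[, 1:2])
    grid <- grid[point_in_polygon(grid[, 1], grid[, 2], poly), , drop = FALSE]
    if (!nrow(grid)) stop("mask removed every grid point", call. = FALSE)
  }
  structure(list(grid = grid, cell_area = resolution^2,
                 total_area = nrow(grid) * resolution^2,
                 buffer = buffer, resolution = resolution),
            class = "rem_state_space")
}

#' @export
print.rem_state_space <- function(x, ...) {
  cat(sprintf("state space: %d points at %.2g km resolution, %.4g km^2 (buffer %.3g km)\n",
              nrow(x$grid), x$resolution, x$total_area, x$buffer))
  invisible(x)
}

#' Even-odd point-in-polygon test
#'
#' Ray-casting membership test used for state-space mask clipping.
#' Vertices may form an open or closed ring.
#'
#' @param px,py Point coordinates (vectorised).
#' @param poly Two-column matrix of polygon vertices.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' SCR detection probability
#'
#' Complementary log-log hazard with a stretched distance kernel:
#' `p(d) = 1 - exp(-exp(alpha0 + beta*b + sex_effect) *
#' exp(-(d^2/sigma^2)^theta_det))`. `theta_det = 1` gives a Gaussian
#' (half-normal) kernel, `theta_det = 0.5` an exponential one. `p(0)` is
#' the baseline detection probability g0 when the offsets are zero.
#'
#' @param d Distance(s), km (>= 0).
#' @param params List with `alpha0`, `sigma`, `theta_det`, and optional
#'   `beta`, `b`, `sex_effect` (all default 0).
#' @return Detection probability, same length as `d`.
#' @export
detection_probability <- function(d, params) {
  sigma <- params$sigma; theta <- params$theta_det
  if (is.null(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (any(d < 0)) stop("d must be >= 0", call. = FALSE)
  eta <- params$alpha0 + (params$beta %||% 0) * (params$b %||% 0) +
    (params$sex_effect %||% 0)
  1 - exp(-exp(eta) * exp(-(d^2 / sigma^2)^theta))
}

#' Convert between g0 and the cloglog baseline alpha0
#'
#' `alpha0 = log(-log(1 - g0))` and its inverse
#' `g0 = 1 - exp(-exp(alpha0))`.
#'
#' @param g0,alpha0 Values to convert.
#' @return The converted value.
#' @export
g0_to_alpha0 <- function(g0) {
  if (any(g0 <= 0 | g0 >= 1)) stop("g0 must be in (0, 1)", call. = FALSE)
  log(-log(1 - g0))
}

#' @rdname g0_to_alpha0
#' @export
alpha0_to_g0 <- function(alpha0) 1 - exp(-exp(alpha0))

#' SCR model specification
#'
#' Covariate structure of the eight candidate models: sex and/or
#' behavioural response on the baseline detection (g0), sex on the
#' movement scale (sigma), plus the data-augmentation size M.
#'
#' @param g0_covariates Subset of `c("sex", "behavior")`.
#' @param sigma_covariates Subset of `c("sex")`.
#' @param M Augmentation size (upper bound on abundance; must exceed the
#'   number of observed individuals).
#' @return Object of class `scr_model_spec`.
#' @export
scr_model_spec <- function(g0_covariates = character(),
                           sigma_covariates = character(), M = 400) {
  if (!all(g0_covariates %in% c("sex", "behavior")))
    stop("g0_covariates must be a subset of {sex, behavior}", call. = FALSE)
  if (!all(sigma_covariates %in% "sex"))
    stop("sigma_covariates must be a subset of {sex}", call. = FALSE)
  structure(list(g0_covariates = g0_covariates,
                 sigma_covariates = sigma_covariates, M = as.integer(M)),
            class = "scr_model_spec")
}

#' MCMC configuration
#'
#' Defaults are the scaled-down test setting (3 chains x 20,000
#' iterations, 5,000 burn-in); the full-scale analysis setting is 3
#' chains of 400,000 with 50,000 burn-in. Proposal scales are adapted
#' during burn-in toward 20-40% acceptance and frozen afterwards.
#'
#' @param n_chains Number of chains.
#' @param n_iterations Iterations per chain.
#' @param n_burnin Burn-in iterations (discarded; must be < n_iterations).
#' @param seed Base seed; chain k uses `seed + k - 1`.
#' @param proposal_scales Initial random-walk SDs for (alpha0, beta,
#'   sex-on-g0, sigma, sex-on-log-sigma, theta).
#' @param center_jump Radius (km) of the local activity-center proposal.
#' @param uniform_prob Probability of proposing a uniform (global)
#'   activity-center move instead of a local one.
#' @param adapt Adapt proposal scales during burn-in.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iterations = 20000, n_burnin = 5000,
                        seed = 1L,
                        proposal_scales = c(0.15, 0.3, 0.3, 0.08, 0.2, 0.1),
                        center_jump = 1.5, uniform_prob = 0.2, adapt = TRUE) {
  if (n_burnin >= n_iterations)
    stop("n_burnin must be < n_iterations", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin), seed = as.integer(seed),
                 proposal_scales = proposal_scales,
                 center_jump = center_jump, uniform_prob = uniform_prob,
                 adapt = adapt),
            class = "mcmc_config")
}

#' Fit the SCR model by MCMC with data augmentation
#'
#' Metropolis-within-Gibbs over the augmented population: inclusion
#' indicators z_i ~ Bernoulli(psi), sexes ~ Bernoulli(psi_sex) where
#' unknown, activity centers on the state-space grid, and random-walk
#' updates of the detection parameters. Priors: flat on alpha0, beta and
#' the sex offsets, flat (0, Inf) on sigma, uniform(0.5, 1) on theta_det,
#' uniform(0, 1) on psi and psi_sex. Starting values follow the reference
#' analysis (sigma = 1, theta = 0.75, alpha0 = -4.01, beta = 0,
#' psi = 0.5, psi_sex = 0.31). Non-convergence is reported through
#' [gelman_rubin()], never as an error.
#'
#' @param history A [capture_history()].
#' @param traps Data frame `trap_id`, `x`, `y` (km); every trap in
#'   `history$trap_ids` must appear.
#' @param space A [build_state_space()] result.
#' @param spec A [scr_model_spec()].
#' @param cfg An [mcmc_config()].
#' @param start Optional named list overriding starting values.
#' @return Object of class `scr_fit`: `chains` (list of post-burn-in draw
#'   matrices with columns alpha0, g0, beta, asex, sigma, ssex, theta,
#'   psi, psi_sex, N, D), plus the model spec, config, space and bookkeeping.
#' @export
run_mcmc <- function(history, traps, space, spec = scr_model_spec(),
                     cfg = mcmc_config(), start = NULL) {
  stopifnot(inherits(history, "capture_history"),
            inherits(space, "rem_state_space"),
            inherits(spec, "scr_model_spec"), inherits(cfg, "mcmc_config"))
  traps <- as.data.frame(traps)
  if (!all(history$trap_ids %in% as.character(traps$trap_id)))
    stop("history references traps missing from the trap table", call. = FALSE)
  n_obs <- length(history$individuals)
  if (spec$M <= n_obs)
    stop("augmentation size M must exceed the number of observed individuals",
         call. = FALSE)
  K <- history$n_occasions
  grid <- space$grid
  G <- nrow(grid)
  tx <- traps$x[match(history$trap_ids, as.character(traps$trap_id))]
  ty <- traps$y[match(history$trap_ids, as.character(traps$trap_id))]
  J <- length(tx)
  d2 <- outer(grid[, 1], tx, "-")^2 + outer(grid[, 2], ty, "-")^2
  logd2 <- log(d2)
  slogd2 <- t(apply(logd2, 1, sort))

  # capture cells in CSR order over individuals
  cap <- history$captures
  ii <- match(cap$individual_id, history$individuals)
  jj <- match(cap$trap_id, history$trap_ids)
  kk <- cap$occasion
  o <- order(ii, kk, jj)
  ii <- ii[o]; jj <- jj[o]; kk <- kk[o]
  first_cap <- rep(K + 1L, n_obs)
  if (n_obs) first_cap <- vapply(seq_len(n_obs), function(i)
    if (any(ii == i)) min(kk[ii == i]) else K + 1L, integer(1))
  cell_c <- as.integer(kk > first_cap[ii])
  n_post <- pmax(0L, K - first_cap)  # occasions with behavioural offset on
  cell_ptr <- c(0L, cumsum(tabulate(ii, nbins = n_obs)))

  sex_obs <- ifelse(history$sex == "M", 1L, ifelse(history$sex == "F", 0L, -1L))

  # starting centers: observed at the grid point nearest their mean
  # capture location, augmented uniform
  centers <- integer(spec$M)
  if (n_obs) {
    mx <- tapply(tx[jj], ii, mean); my <- tapply(ty[jj], ii, mean)
    for (i in seq_len(n_obs)) {
      centers[i] <- which.min((grid[, 1] - mx[[as.character(i)]])^2 +
                                (grid[, 2] - my[[as.character(i)]])^2) - 1L
    }
  }
  st <- list(alpha0 = -4.01, beta = 0, asex = 0, sigma = 1, ssex = 0,
             theta = 0.75, psi = 0.5, psi_sex = 0.31)
  if (!is.null(start)) st[names(start)] <- start
  ctrl <- list(n_iterations = cfg$n_iterations, n_burnin = cfg$n_burnin,
               center_jump = cfg$center_jump, uniform_prob = cfg$uniform_prob,
               proposal_scales = cfg$proposal_scales, adapt = cfg$adapt)
  chains <- vector("list", cfg$n_chains)
  acc <- numeric(cfg$n_chains)
  for (ch in seq_len(cfg$n_chains)) {
    set.seed(cfg$seed + ch - 1L)
    aug_centers <- centers
    if (spec$M > n_obs)
      aug_centers[(n_obs + 1L):spec$M] <- sample.int(G, spec$M - n_obs,
                                                     replace = TRUE) - 1L
    st$centers <- as.integer(aug_centers)
    res <- scr_mcmc_chain(n_obs, spec$M, K,
                          as.integer(cell_ptr), as.integer(jj - 1L),
                          cell_c, as.integer(n_post), as.integer(sex_obs),
                          logd2, slogd2, grid, space$cell_area,
                          "sex" %in% spec$g0_covariates,
                          "behavior" %in% spec$g0_covariates,
                          "sex" %in% spec$sigma_covariates,
                          st, ctrl)
    chains[[ch]] <- res$draws
    acc[ch] <- res$accept_center
  }
  structure(list(chains = chains, spec = spec, cfg = cfg, space = space,
                 n_obs = n_obs, accept_center = acc),
            class = "scr_fit")
}

#' @export
print.scr_fit <- function(x, ...) {
  d <- density_posterior(x)
  cat(sprintf("SCR fit: %d observed individuals, M = %d, %d chains x %d draws (post burn-in)\n",
              x$n_obs, x$spec$M, length(x$chains), nrow(x$chains[[1]])))
  cat(sprintf("  density: %.3f /km^2 (%.2f /10 km^2), 95%% CrI [%.2f, %.2f] /10 km^2\n",
              d["mean"], 10 * d["mean"], 10 * d["lower"], 10 * d["upper"]))
  for (p in c("sigma", "g0", "theta"))
    cat(sprintf("  %s: Rhat = %.3f\n", p, gelman_rubin(x, p)))
  invisible(x)
}

pooled_draws <- function(fit, parameter) {
  unlist(lapply(fit$chains, function(m) m[, parameter]), use.names = FALSE)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' `Rhat = sqrt(((n-1)/n * W + B/n) / W)` with B the between-chain and W
#' the within-chain variance, computed over the stored post-burn-in
#' draws. Values below 1.1 are taken as converged in the reference
#' analysis. Note that chains that agree perfectly give
#' `sqrt((n-1)/n)`, marginally below 1, as in every classical PSRF
#' implementation.
#'
#' @param fit An `scr_fit`, or a list of numeric vectors/matrices (one
#'   per chain).
#' @param parameter Column name when matrices are supplied.
#' @return The PSRF (unitless).
#' @export
gelman_rubin <- function(fit, parameter = NULL) {
  chains <- if (inherits(fit, "scr_fit")) fit$chains else fit
  if (!is.null(parameter) && is.matrix(chains[[1]]))
    chains <- lapply(chains, function(m) m[, parameter])
  m <- length(chains)
  if (m < 2) stop("need at least 2 chains", call. = FALSE)
  n <- length(chains[[1]])
  if (n < 2) stop("need at least 2 draws per chain", call. = FALSE)
  means <- vapply(chains, mean, numeric(1))
  W <- mean(vapply(chains, var, numeric(1)))
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior density summary
#'
#' Realized abundance N divided by the state-space area, summarised over
#' the pooled post-burn-in chains.
#'
#' @param fit An `scr_fit`.
#' @param space Optional state space (defaults to the one used to fit).
#' @return Named vector `mean`, `lower`, `upper` (2.5/97.5% quantiles),
#'   individuals per km^2.
#' @export
density_posterior <- function(fit, space = NULL) {
  stopifnot(inherits(fit, "scr_fit"))
  area <- (space %||% fit$space)$total_area
  d <- pooled_draws(fit, "N") / area
  c(mean = mean(d), lower = quantile(d, 0.025, names = FALSE),
    upper = quantile(d, 0.975, names = FALSE))
}

# exact first/last-occasion span moments for n captures among K
# occasions: the capture occasions of an individual caught n times form a
# uniformly random n-subset of {1..K} under the closed-population null
span_moments <- function(n, K) {
  s <- (n - 1):(K - 1)
  cnt <- (K - s) * choose(s - 1, n - 2)
  p <- cnt / choose(K, n)
  mu <- sum(s * p)
  c(mu = mu, v = sum(s^2 * p) - mu^2)
}

#' Otis et al. (1978) demographic closure test
#'
#' For each individual captured on two or more occasions, the span
#' between first and last capture occasion is compared with its exact
#' null moments under closure (capture occasions exchangeable); the
#' standardized sum is referred to the standard normal lower tail,
#' `p = pnorm(z)`. Small p (short spans) indicates closure failure:
#' animals present during only part of the study. Optionally a
#' permutation null (capture occasions resampled within individuals)
#' provides a direction check.
#'
#' @param history A [capture_history()].
#' @param n_perm Permutation resamples for `p_perm` (0 = skip).
#' @return Object of class `closure_test`: `z`, `p`, `n_recaptured`, and
#'   `p_perm` when requested.
#' @export
otis_closure_test <- function(history, n_perm = 0) {
  stopifnot(inherits(history, "capture_history"))
  K <- history$n_occasions
  occ <- lapply(split(history$captures$occasion, history$captures$individual_id),
                unique)
  occ <- occ[lengths(occ) >= 2]
  if (!length(occ))
    stop("closure test needs at least one individual captured on >= 2 occasions",
         call. = FALSE)
  spans <- vapply(occ, function(o) diff(range(o)), numeric(1))
  ns <- lengths(occ)
  mom <- vapply(ns, span_moments, numeric(2), K = K)
  z <- (sum(spans) - sum(mom["mu", ])) / sqrt(sum(mom["v", ]))
  out <- list(z = z, p = pnorm(z), n_recaptured = length(occ))
  if (n_perm > 0) {
    tot <- vapply(seq_len(n_perm), function(b) {
      sum(vapply(ns, function(n) diff(range(sample.int(K, n))), numeric(1)))
    }, numeric(1))
    out$p_perm <- (sum(tot <= sum(spans)) + 1) / (n_perm + 1)
  }
  structure(out, class = "closure_test")
}

#' @export
print.closure_test <- function(x, ...) {
  cat(sprintf("Otis closure test: Z = %.2f, p = %.2f (%d recaptured individuals)\n",
              x$z, x$p, x$n_recaptured))
  if (!is.null(x$p_perm)) cat(sprintf("  permutation p = %.3f\n", x$p_perm))
  invisible(x)
}

#' Brute-force marginal log-likelihood of observed capture histories
#'
#' For each observed individual, the binomial likelihood of its trap
#' counts is averaged over every state-space grid point (uniform
#' activity-center prior) and the logs are summed. Independent of the
#' MCMC code path; used as an oracle on small instances. Behavioural
#' effects are not supported here.
#'
#' @param history A [capture_history()].
#' @param traps Trap table (`trap_id`, `x`, `y`).
#' @param space A [build_state_space()] result.
#' @param params List with `alpha0`, `sigma`, `theta_det`.
#' @return Total log-likelihood (scalar).
#' @export
scr_marginal_loglik <- function(history, traps, space, params) {
  stopifnot(inherits(history, "capture_history"))
  K <- history$n_occasions
  tx <- traps$x[match(history$trap_ids, as.character(traps$trap_id))]
  ty <- traps$y[match(history$trap_ids, as.character(traps$trap_id))]
  grid <- space$grid
  d <- sqrt(outer(grid[, 1], tx, "-")^2 + outer(grid[, 2], ty, "-")^2)
  p <- detection_probability(d, params)       # G x J
  l1p <- log1p(-p)
  total <- 0
  for (id in history$individuals) {
    capi <- history$captures[history$captures$individual_id == id, ]
    y <- tabulate(match(capi$trap_id, history$trap_ids),
                  nbins = length(history$trap_ids))
    pos <- y > 0   # log(p) only where captures occurred (p can underflow)
    ll_g <- log(p[, pos, drop = FALSE]) %*% y[pos] + l1p %*% (K - y)
    mx <- max(ll_g)
    total <- total + if (is.finite(mx)) mx + log(mean(exp(ll_g - mx))) else -Inf
  }
  as.numeric(total)
}
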