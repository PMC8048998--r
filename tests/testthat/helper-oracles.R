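# Independent oracles, kept deliberately separate from the package's own
# algorithms: brute-force enumeration for the marginal likelihood, the
# closed-form conjugate posterior for known-variance regression, and a
# Monte-Carlo point-in-polygon area estimator.

# Marginal likelihood by exhaustive enumeration over all 3^T latent paths.
# Transitions Binomial(z_t | z_{t-1}, phi) from z_1 = 2; observation factor
# Binomial(y_t | z_t, p_t) wherever y is non-missing.
enumerate_loglik <- function(y, phi, p) {
  T <- length(y)
  p <- rep_len(p, T)
  states <- expand.grid(rep(list(0:2), T))
  total <- 0
  for (r in seq_len(nrow(states))) {
    z <- as.integer(states[r, ])
    w <- if (z[1] == 2) 1 else 0
    if (w > 0 && T >= 2) {
      for (t in 2:T) w <- w * dbinom(z[t], z[t - 1], phi)
    }
    if (w > 0) {
      for (t in seq_len(T)) {
        if (!is.na(y[t])) w <- w * dbinom(y[t], z[t], p[t])
      }
    }
    total <- total + w
  }
  log(total)
}

# Conjugate posterior for y = X b + e, e ~ N(0, sigma^2) with sigma known
# and prior b ~ N(0, prior_sd^2 I): returns posterior mean and covariance.
conjugate_lm_posterior <- function(x, y, sigma, prior_sd) {
  X <- cbind(1, x)
  Vinv <- crossprod(X) / sigma^2 + diag(1 / prior_sd^2, 2)
  V <- solve(Vinv)
  m <- V %*% (crossprod(X, y) / sigma^2)
  list(mean = as.numeric(m), cov = V)
}

# Monte-Carlo estimate of the fraction of a disc of radius `rho` (centred at
# the origin) covered by a polygon, by uniform sampling in the disc.
mc_disc_coverage <- function(ring, rho, n = 1e5) {
  r <- rho * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  px <- r * cos(th); py <- r * sin(th)
  inside <- sp::point.in.polygon(px, py, ring[, 1], ring[, 2]) > 0
  mean(inside)
}

# Small deterministic observation matrix builder for fit tests.
all_twos_series <- function(n_nests = 5, T_days = 60, hatch = 31) {
  y <- matrix(NA_integer_, T_days, n_nests)
  y[hatch:T_days, ] <- 2L
  tibble::tibble(
    site_id = "S1", year_id = "Y1",
    nest_id = rep(sprintf("n%02d", seq_len(n_nests)), each = T_days),
    t = rep(seq_len(T_days), n_nests),
    count = as.integer(y)
  )
}

fast_mcmc <- function(seed = 1L, n_chains = 2) {
  mcmc_config(n_chains = n_chains, n_warmup = 500, n_samples = 1500,
              thin = 2, rng_seed = seed)
}
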