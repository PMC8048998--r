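test_that("perfect-detection no-mortality data give a point mass at BS = 2", {
  obs <- all_twos_series(n_nests = 5)
  fit <- suppressWarnings(
    fit_survival_model(obs, mcmc = fast_mcmc(seed = 2)))
  bs <- breeding_success(fit, summarise = FALSE)
  expect_true(all(bs$bs == 2))
  tc <- total_chicks(fit, "S1", "Y1")
  # day 1 is exactly twice the nest count with zero posterior sd
  expect_equal(tc$Z_mean[1], 10)
  expect_equal(tc$Z_sd[1], 0)
  # with all-twos observations the latent states are pinned wherever observed
  expect_true(all(tc$Z_mean[31:60] == 10))
})

test_that("posterior-mean total-chick trajectories are non-increasing", {
  ds <- simulate_dataset(sim_config(n_site_years = 2, n_nests = 10,
                                    rng_seed = 21))
  fit <- suppressWarnings(fit_survival_model(ds, mcmc = fast_mcmc(seed = 3)))
  for (j in seq_len(2)) {
    tr <- total_chicks(fit, ds$sims[[j]]$site_id, ds$sims[[j]]$year_id)
    expect_true(all(diff(tr$Z_mean) <= 1e-9))
  }
  bs <- breeding_success(fit, summarise = FALSE)
  expect_true(all(bs$bs >= 0 & bs$bs <= 2))
})

test_that("a site/year with no observations is rejected with advice", {
  obs <- all_twos_series(n_nests = 3)
  obs$count <- NA_integer_
  expect_error(fit_survival_model(obs), "zero observed values; exclude")
})

test_that("invalid counts are rejected before sampling", {
  obs <- all_twos_series(n_nests = 3)
  obs$count[obs$t == 40] <- 3L
  expect_error(suppressWarnings(fit_survival_model(obs, mcmc = fast_mcmc())))
})

test_that("tidy and glance expose the fit in broom shapes", {
  ds <- simulate_dataset(sim_config(n_site_years = 2, n_nests = 8,
                                    rng_seed = 5))
  fit <- suppressWarnings(fit_survival_model(ds, mcmc = fast_mcmc(seed = 4)))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "conf.low", "conf.high",
                    "rhat", "ess_per_chain") %in% names(td)))
  expect_true(all(c("theta_phi", "sigma_mu_phi", "mu_p", "mu_phi[1]",
                    "beta_p[2]") %in% td$term))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  g <- glance(fit)
  expect_equal(g$n_site_years, 2L)
  expect_equal(g$n_chains, 2L)
  dr <- posterior_draws(fit)
  expect_setequal(names(dr), c("draw", "chain", "parameter", "value"))
  expect_equal(nrow(dr), nrow(fit$draws) * ncol(fit$draws))
  expect_equal(dr$value[dr$parameter == "theta_phi"],
               unname(fit$draws[, "theta_phi"]))
  # survival and sd draws respect their supports
  expect_true(all(fit$draws[, "sigma_mu_phi"] > 0))
  expect_true(all(plogis(fit$draws[, "mu_phi[1]"]) > 0 &
                    plogis(fit$draws[, "mu_phi[1]"]) < 1))
})

test_that("convergence failure warns rather than errors", {
  ds <- simulate_dataset(sim_config(n_site_years = 2, n_nests = 8,
                                    rng_seed = 6))
  expect_warning(
    fit_survival_model(ds, mcmc = mcmc_config(n_chains = 2, n_warmup = 50,
                                              n_samples = 80, thin = 1,
                                              rng_seed = 1)),
    "convergence|effective sample")
})

test_that("posterior predictive replicates respect the data's structure", {
  ds <- simulate_dataset(sim_config(n_site_years = 2, n_nests = 10,
                                    rng_seed = 33))
  fit <- suppressWarnings(fit_survival_model(ds, mcmc = fast_mcmc(seed = 7)))
  set.seed(1)
  ppc <- posterior_predictive_check(fit, statistic = "daily_total", n_rep = 50)
  # per-day rows only where the data could be observed; p-values are proper
  expect_true(all(ppc$per_day$p_value >= 0 & ppc$per_day$p_value <= 1))
  expect_true(all(ppc$per_day$t >= 31))
  set.seed(1)
  p2 <- posterior_predictive_check(fit, statistic = "n_detections", n_rep = 50)
  expect_true(p2$p_value >= 0 && p2$p_value <= 1)
  expect_error(posterior_predictive_check(fit, statistic = "nope"))
})

test_that("model-generated data yield calibrated Bayesian p-values", {
  # data simulated from the model itself should rarely flag misfit
  pvals <- vapply(1:10, function(r) {
    ds <- simulate_dataset(sim_config(n_site_years = 1, n_nests = 12,
                                      rng_seed = 300 + r))
    fit <- suppressWarnings(
      fit_survival_model(ds, mcmc = fast_mcmc(seed = 400 + r)))
    set.seed(500 + r)
    posterior_predictive_check(fit, n_rep = 100)$p_value
  }, 1.0)
  expect_gte(sum(pvals > 0.05 & pvals < 0.95), 8)
})
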