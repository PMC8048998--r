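test_that("degenerate survival and detection produce deterministic data", {
  # survival and detection effectively 1 (saturated logits)
  cfg <- sim_config(n_nests = 10, theta_phi = 1000, sigma_mu_phi = 0,
                    mu_p = 1000, mu_beta_p = 0, sigma_beta_p = 0,
                    sigma_nu_p = 0, hatch_day = 1, rng_seed = 2)
  sim <- simulate_site_year(cfg, 1)
  expect_true(all(sim$z == 2L))
  expect_true(all(sim$y == 2L))
  # survival effectively 0: everything dies at t = 2
  cfg0 <- sim_config(n_nests = 10, theta_phi = -1000, sigma_mu_phi = 0,
                     mu_p = 1000, mu_beta_p = 0, sigma_beta_p = 0,
                     sigma_nu_p = 0, hatch_day = 1, rng_seed = 2)
  sim0 <- simulate_site_year(cfg0, 1)
  expect_true(all(sim0$z[2:60, ] == 0L))
  expect_true(all(sim0$y[2:60, ] == 0L))
})

test_that("mean final latent count matches the closed form 2 * phi^(T-1)", {
  phi <- 0.995
  cfg <- sim_config(n_nests = 50, theta_phi = qlogis(phi), sigma_mu_phi = 0,
                    rng_seed = 31)
  sim <- simulate_site_year(cfg, 1)
  expected <- 2 * phi^59
  se <- sqrt(2 * phi^59 * (1 - phi^59) / 50)
  expect_lt(abs(mean(sim$z[60, ]) - expected), 3 * se)
})

test_that("simulated datasets satisfy the structural invariants", {
  cfg <- sim_config(n_site_years = 4, n_nests = 15, rng_seed = 17,
                    p_outage = 0.1)
  ds <- simulate_dataset(cfg)
  for (sim in ds$sims) {
    expect_true(all(sim$z[1, ] == 2L))
    expect_true(all(apply(sim$z, 2, function(v) all(diff(v) <= 0))))
    obs <- !is.na(sim$y)
    expect_true(all(sim$y[obs] <= sim$z[obs]))
    expect_true(all(is.na(sim$y[seq_len(cfg$hatch_day - 1), ])))
  }
  # bit-identical under the same config and seed
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds$sims[[2]]$z, ds2$sims[[2]]$z)
  expect_identical(ds$sims[[2]]$y, ds2$sims[[2]]$y)
})

test_that("expected daily chick loss declines over the season when phi is constant", {
  # E[Z_{t-1} - Z_t] = (1 - phi) E[Z_{t-1}] shrinks as chicks are lost
  cfg <- sim_config(n_nests = 50, theta_phi = qlogis(0.99), sigma_mu_phi = 0)
  losses <- replicate(50, {
    sim <- simulate_site_year(sim_config(n_nests = 50,
                                         theta_phi = qlogis(0.99),
                                         sigma_mu_phi = 0,
                                         rng_seed = sample.int(1e6, 1)), 1)
    Z <- rowSums(sim$z)
    c(egg = (Z[1] - Z[30]) / 30, old = (Z[45] - Z[60]) / 15)
  })
  expect_gt(mean(losses["egg", ]), mean(losses["old", ]))
})

test_that("extreme event injection rescales one day's survival", {
  cfg <- sim_config(n_nests = 30, rng_seed = 9)
  sim <- simulate_site_year(cfg, 1)
  # zero drop reproduces the input exactly (same seed replay)
  same <- inject_extreme_event(sim, event_day = 40, survival_drop = 0)
  expect_identical(same$z, sim$z)
  expect_identical(same$y, sim$y)
  # total drop kills everything from the event day on
  dead <- inject_extreme_event(sim, event_day = 40, survival_drop = 1)
  expect_true(all(dead$z[40:60, ] == 0L))
  # event recorded as magnitude-3 snow
  ev <- dead$covariates$precip
  expect_true(any(ev$day == 40 & ev$kind == "snow" & ev$magnitude == 3))
  # half drop at phi ~ 1: E[Z_40] = 0.5 * Z_39
  cfg1 <- sim_config(n_nests = 200, theta_phi = 1000, sigma_mu_phi = 0,
                     rng_seed = 4)
  sim1 <- simulate_site_year(cfg1, 1)
  half <- inject_extreme_event(sim1, event_day = 40, survival_drop = 0.5)
  Z39 <- sum(half$z[39, ])  # 400, no mortality before the event
  Z40 <- sum(half$z[40, ])
  se <- sqrt(Z39 * 0.5 * 0.5)
  expect_lt(abs(Z40 - 0.5 * Z39), 4 * se)
})

test_that("driver simulation has the stated degenerate and null behaviour", {
  exact <- simulate_drivers(n_site_years = 10, alpha = 0.5, beta = 0.1,
                            sigma = 0, sigma_bs_range = c(0, 0),
                            covariate_generator = function(n) seq_len(n),
                            rng_seed = 3)
  expect_equal(exact$bs_obs, 0.5 + 0.1 * seq_len(10), tolerance = 1e-12)
  null <- simulate_drivers(n_site_years = 1000, beta = 0, rng_seed = 5)
  expect_lt(abs(cor(null$bs_obs, null$x)), 0.2)
  expect_identical(simulate_drivers(rng_seed = 8), simulate_drivers(rng_seed = 8))
})
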