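test_that("precipitation events count only magnitudes two and above", {
  sc <- tibble::tibble(kind = c("rain", "rain", "snow", "rain", "snow"),
                       magnitude = c(1, 2, 3, 1, 2))
  expect_equal(count_precip_events(sc), 3)
  expect_equal(count_precip_events(sc[0, ]), 0L)
  expect_equal(count_precip_events(tibble::tibble(kind = "rain", magnitude = 1)), 0)
  expect_error(count_precip_events(tibble::tibble(kind = "rain", magnitude = 4)),
               "magnitude")
})

test_that("tourism window is inclusive on both endpoints", {
  lay <- as.Date("2014-12-03"); creche <- as.Date("2015-02-01")
  v <- tibble::tibble(date = c(lay, lay + 30, creche + 1),
                      visitors = c(50, 70, 30))
  expect_equal(tourism_window_count(v, lay, creche), 120L)
  expect_equal(tourism_window_count(
    tibble::tibble(date = lay - 1, visitors = 99), lay, creche), 0L)
  expect_equal(tourism_window_count(
    tibble::tibble(date = lay, visitors = 120), lay, creche), 120L)
})

test_that("noiseless driver data recover the slope almost exactly", {
  tab <- tibble::tibble(x = seq(0, 20, length.out = 15),
                        bs_obs = 0.5 + 0.1 * seq(0, 20, length.out = 15),
                        sigma_bs = 1e-8)
  fit <- fit_driver_regression(tab, "x", n_chains = 2, n_warmup = 500,
                               n_samples = 1500, rng_seed = 2)
  expect_lt(abs(glance(fit)$beta_median - 0.1), 1e-3)
})

test_that("with sigma_bs = 0 and fixed sigma the posterior is conjugate", {
  set.seed(30)
  x <- runif(20, 0, 10)
  yobs <- 1.2 - 0.05 * x + rnorm(20, 0, 0.3)
  tab <- tibble::tibble(x = x, bs_obs = yobs, sigma_bs = 0)
  fit <- fit_driver_regression(tab, "x", sigma_fixed = 0.3, prior_sd = 10,
                               n_chains = 2, n_warmup = 500,
                               n_samples = 4000, rng_seed = 3)
  oracle <- conjugate_lm_posterior(x, yobs, sigma = 0.3, prior_sd = 10)
  td <- tidy(fit)
  mcse <- sqrt(diag(oracle$cov)) / sqrt(200)  # generous effective-draw floor
  expect_lt(abs(td$mean[td$term == "alpha"] - oracle$mean[1]), 4 * mcse[1])
  expect_lt(abs(td$mean[td$term == "beta"] - oracle$mean[2]), 4 * mcse[2])
  expect_equal(td$std.error[td$term == "alpha"], sqrt(oracle$cov[1, 1]),
               tolerance = 0.05)
  expect_equal(td$std.error[td$term == "beta"], sqrt(oracle$cov[2, 2]),
               tolerance = 0.05)
})

test_that("with flat priors and sigma_bs = 0 the fit matches least squares", {
  set.seed(31)
  x <- runif(25, 0, 10)
  yobs <- 0.8 + 0.07 * x + rnorm(25, 0, 0.2)
  tab <- tibble::tibble(x = x, bs_obs = yobs, sigma_bs = 0)
  fit <- fit_driver_regression(tab, "x", prior_sd = 100,
                               n_chains = 2, n_warmup = 500,
                               n_samples = 3000, rng_seed = 5)
  ols <- coef(lm(yobs ~ x))
  td <- tidy(fit)
  expect_equal(td$mean[td$term == "alpha"], unname(ols[1]), tolerance = 0.02)
  expect_equal(td$mean[td$term == "beta"], unname(ols[2]), tolerance = 0.01)
})

test_that("inflating the measurement sd never narrows the slope interval", {
  set.seed(32)
  tab <- simulate_drivers(n_site_years = 20, rng_seed = 6)
  tab$precip <- tab$x
  f1 <- fit_driver_regression(tab |> dplyr::mutate(sigma_bs = 0.02),
                              "precip", n_chains = 2, rng_seed = 7)
  f2 <- fit_driver_regression(tab |> dplyr::mutate(sigma_bs = 0.4),
                              "precip", n_chains = 2, rng_seed = 7)
  w1 <- glance(f1)$beta_high - glance(f1)$beta_low
  w2 <- glance(f2)$beta_high - glance(f2)$beta_low
  expect_gte(w2, w1)
})

test_that("the krill covariate is log-transformed with a recorded zero offset", {
  tab <- tibble::tibble(krill_catch = c(0, 10, 100, 1000, 250, 30),
                        bs_obs = c(1.5, 1.4, 1.3, 1.1, 1.2, 1.45),
                        sigma_bs = 0.05)
  fit <- fit_driver_regression(tab, "krill_catch", n_chains = 2,
                               n_warmup = 300, n_samples = 800, rng_seed = 8)
  expect_true(fit$log_transformed)
  expect_equal(fit$log_offset, 5)  # half the smallest positive catch
  expect_equal(fit$data$x[1], log(5))
  tab$krill_catch[1] <- -1
  expect_error(fit_driver_regression(tab, "krill_catch"), "negative")
})

test_that("regression posterior matches an independent JAGS fit", {
  skip_if_not_installed("rjags")
  set.seed(33)
  tab <- simulate_drivers(n_site_years = 15, alpha = 1.4, beta = -0.02,
                          sigma = 0.15, rng_seed = 9)
  fit <- fit_driver_regression(tab, "x", log_covariate = FALSE,
                               n_chains = 2, rng_seed = 10)
  model_str <- "model {
    for (i in 1:n) {
      bs_obs[i] ~ dnorm(bs_true[i], pow(sigma_bs[i], -2))
      bs_true[i] ~ dnorm(alpha + beta * x[i], pow(sigma, -2))
    }
    alpha ~ dnorm(0, 0.01)
    beta ~ dnorm(0, 0.01)
    sigma ~ dnorm(0, 1) T(0,)
  }"
  jm <- rjags::jags.model(textConnection(model_str),
                          data = list(n = nrow(tab), bs_obs = tab$bs_obs,
                                      sigma_bs = tab$sigma_bs, x = tab$x),
                          n.chains = 2, n.adapt = 1000, quiet = TRUE)
  sm <- rjags::coda.samples(jm, c("alpha", "beta", "sigma"), n.iter = 8000)
  ref <- summary(sm)$statistics
  td <- tidy(fit)
  for (p in c("alpha", "beta", "sigma")) {
    expect_equal(td$mean[td$term == p], unname(ref[p, "Mean"]),
                 tolerance = 0.03)
    expect_equal(td$std.error[td$term == p], unname(ref[p, "SD"]),
                 tolerance = 0.15)
  }
})

test_that("event overlay exports one row per day with flagged events", {
  z <- tibble::tibble(t = 1:60, Z_mean = seq(40, 25, length.out = 60),
                      Z_sd = rep(1, 60))
  ev <- tibble::tibble(day = 43L, kind = "snow", magnitude = 3L)
  out <- event_overlay_export(z, ev)
  expect_equal(out$t, 1:60)
  expect_equal(sum(!is.na(out$event_magnitude)), 1)
  expect_equal(out$event_magnitude[43], 3L)
  none <- event_overlay_export(z, NULL)
  expect_true(all(is.na(none$event_kind)))
})
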